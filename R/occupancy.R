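# Occupancy intervals: each sample owns the half-open interval from its own
# timestamp to the next sample's (the last sample runs to the window end), so
# summed interval time equals covered time exactly.
occupancy_dt <- function(times, end_s) {
  c(diff(times), end_s - times[length(times)])
}

#' CS+ preference fraction of a trajectory phase
#'
#' Time-weighted fraction of a phase that the fish spends on the CS+ half of
#' the tank (arena split at the midline of the length axis), honouring the
#' scheduled side changes: the alternation cadence during baseline and the
#' mid-probe CS+/CS- swap.  Each inter-sample interval is split at the
#' scheduled side-change times, so a fish sitting still through the probe swap
#' scores exactly 0.5.
#'
#' If the trajectory leaves an internal gap longer than `gap_tol_s` inside the
#' phase a warning is raised and the fraction is computed over the covered
#' time only.
#'
#' @param traj Trajectory tibble (`subject_id`, `time_s`, `u`, `v`), top view,
#'   with `u` along the tank length.
#' @param schedule A [conditioning_schedule()].
#' @param phase `"baseline"` or `"probe"`.
#' @param midline_cm Split point of the length axis; defaults to half the
#'   schedule's tank length.
#' @param gap_tol_s Largest tolerated internal sampling gap, in seconds.
#' @return A tibble `subject_id`, `phase`, `covered_s`, `cs_plus_fraction`.
#' @export
preference_fraction <- function(traj, schedule = conditioning_schedule(),
                                phase = c("baseline", "probe"),
                                midline_cm = schedule$tank_length_cm / 2,
                                gap_tol_s = 1) {
  phase <- match.arg(phase)
  stopifnot(inherits(schedule, "conditioning_schedule"))
  win <- schedule$phases[schedule$phases$phase == phase, ]
  seg <- cs_side_segments(schedule, phase)
  one <- function(df) {
    sid <- df$subject_id[1]
    df <- df[df$time_s >= win$start_s & df$time_s < win$end_s, ]
    if (nrow(df) == 0) {
      warn(sprintf("no trajectory samples inside the %s phase for subject %s",
                   phase, sid))
      return(tibble::tibble(
        subject_id = character(), phase = character(),
        covered_s = numeric(), cs_plus_fraction = numeric()
      ))
    }
    dt <- occupancy_dt(df$time_s, win$end_s)
    over <- dt > gap_tol_s
    if (any(over)) {
      warn(sprintf(
        "sampling gap of %.2f s inside the %s phase for subject %s; fraction computed over covered time",
        max(dt), phase, df$subject_id[1]
      ))
      dt[over] <- 0 # untracked stretches are excluded, not imputed
    }
    fish_side <- ifelse(df$u < midline_cm, "left", "right")
    start <- df$time_s
    end <- df$time_s + dt
    on_cs <- vapply(seq_len(nrow(df)), function(i) {
      ov <- pmin(end[i], seg$end_s) - pmax(start[i], seg$start_s)
      sum(pmax(ov, 0)[seg$side == fish_side[i]])
    }, numeric(1))
    tibble::tibble(
      subject_id = df$subject_id[1],
      phase = phase,
      covered_s = sum(dt),
      cs_plus_fraction = sum(on_cs) / sum(dt)
    )
  }
  traj |>
    dplyr::arrange(.data$subject_id, .data$time_s) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_split() |>
    lapply(one) |>
    dplyr::bind_rows()
}

#' Baseline vs probe CS+ preference
#'
#' Convenience wrapper scoring both phases of the avoidance assay and their
#' difference.  Learned avoidance shows as `delta_pref < 0`: less time near
#' CS+ in the probe than at baseline.
#'
#' @inheritParams preference_fraction
#' @return A tibble `subject_id`, `baseline_pref`, `probe_pref`, `delta_pref`.
#' @export
conditioning_preference <- function(traj, schedule = conditioning_schedule(),
                                    midline_cm = schedule$tank_length_cm / 2,
                                    gap_tol_s = 1) {
  base <- preference_fraction(traj, schedule, "baseline", midline_cm, gap_tol_s)
  probe <- preference_fraction(traj, schedule, "probe", midline_cm, gap_tol_s)
  dplyr::full_join(
    dplyr::select(base, "subject_id", baseline_pref = "cs_plus_fraction"),
    dplyr::select(probe, "subject_id", probe_pref = "cs_plus_fraction"),
    by = "subject_id"
  ) |>
    dplyr::mutate(delta_pref = .data$probe_pref - .data$baseline_pref)
}

#' Novel-tank endpoints
#'
#' Scores the diving assay from paired front- and top-view trajectories of the
#' same recording: time in each of three equal horizontal depth thirds
#' (bottom/middle/top of the tank height, from the front view), total distance
#' travelled (summed Euclidean step lengths in the top view), immobility
#' (total time in runs where top-view speed stays below
#' `cfg$immobility_speed_cms` for at least `cfg$immobility_min_duration_s`)
#' and thigmotaxis (time within `cfg$thigmotaxis_margin_cm` of any wall in the
#' top view).
#'
#' The two views must share subjects and sample times (they are two cameras on
#' one trial); mismatched time bases are a data error.  Thirds times sum to
#' the covered trial time.
#'
#' @param traj_front Front-view trajectory (`v` = height above the tank floor,
#'   cm).
#' @param traj_top Top-view trajectory (`u` along the length, `v` across the
#'   width).
#' @param cfg A [session_config()] carrying tank dimensions and thresholds.
#' @return A tibble with one row per subject: `subject_id`, `covered_s`,
#'   `distance_cm`, `time_bottom_s`, `time_middle_s`, `time_top_s`,
#'   `immobility_s`, `thigmotaxis_s`.
#' @export
tank_endpoints <- function(traj_front, traj_top, cfg = session_config()) {
  stopifnot(inherits(cfg, "session_config"))
  fr <- dplyr::arrange(traj_front, .data$subject_id, .data$time_s)
  tp <- dplyr::arrange(traj_top, .data$subject_id, .data$time_s)
  if (!setequal(unique(fr$subject_id), unique(tp$subject_id)) ||
      nrow(fr) != nrow(tp) ||
      any(fr$subject_id != tp$subject_id) ||
      any(abs(fr$time_s - tp$time_s) > 1e-6)) {
    data_error("front and top trajectories have mismatched time bases")
  }
  third <- cfg$tank_height_cm / 3
  one <- function(f, t) {
    n <- nrow(t)
    end_s <- t$time_s[n]
    dt <- occupancy_dt(t$time_s, end_s) # last interval is 0: window ends at last sample
    covered <- end_s - t$time_s[1]
    slab <- pmin(floor(f$v / third), 2) # 0 bottom, 1 middle, 2 top (v = height)
    step <- sqrt(diff(t$u)^2 + diff(t$v)^2)
    gap <- diff(t$time_s)
    speed <- step / gap
    # immobility: runs of sub-threshold speed lasting long enough
    imm <- 0
    if (length(speed) > 0) {
      r <- rle(speed < cfg$immobility_speed_cms)
      idx_end <- cumsum(r$lengths)
      idx_start <- idx_end - r$lengths + 1
      for (k in seq_along(r$lengths)) {
        if (!r$values[k]) next
        dur <- sum(gap[idx_start[k]:idx_end[k]])
        if (dur >= cfg$immobility_min_duration_s) imm <- imm + dur
      }
    }
    m <- cfg$thigmotaxis_margin_cm
    near_wall <- t$u <= m | t$u >= cfg$tank_length_cm - m |
      t$v <= m | t$v >= cfg$tank_width_cm - m
    tibble::tibble(
      subject_id = t$subject_id[1],
      covered_s = covered,
      distance_cm = sum(step),
      time_bottom_s = sum(dt[slab == 0]),
      time_middle_s = sum(dt[slab == 1]),
      time_top_s = sum(dt[slab == 2]),
      immobility_s = imm,
      thigmotaxis_s = sum(dt[near_wall])
    )
  }
  ids <- unique(tp$subject_id)
  purrr::map(ids, function(id) {
    one(fr[fr$subject_id == id, ], tp[tp$subject_id == id, ])
  }) |>
    dplyr::bind_rows()
}
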