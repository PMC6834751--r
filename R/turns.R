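#' Convert arm-entry events to left/right turn sequences
#'
#' Each passage from one arm to a *different* arm is a binary choice: with the
#' default convention a transition to the clockwise neighbour (viewed from
#' above) codes `R` and to the counterclockwise neighbour `L`.  Centre-zone
#' entries carry no direction and are ignored for coding; consecutive duplicate
#' zone records are collapsed; entries dwelt in for less than
#' `geometry$debounce_s` are discarded before coding.  Re-entering the same arm
#' (arm to centre and back) completes no choice and emits no token; such
#' re-entries, and centre visits, are counted per subject in the `qc`
#' attribute.
#'
#' A subject with fewer than two distinct arm entries yields no turns (not an
#' error).
#'
#' @param events Tibble with columns `subject_id`, `time_s`, `zone`, sorted by
#'   time within subject (as returned by [read_arm_entries()]).
#' @param geometry A [maze_geometry()].
#' @return A tibble with columns `subject_id`, `token` (`"L"`/`"R"`), `time_s`
#'   (entry time into the new arm), with a `qc` attribute tibble
#'   (`subject_id`, `n_events`, `n_centre`, `n_same_arm_reentries`, `n_turns`).
#' @examples
#' ev <- tibble::tibble(
#'   subject_id = "f1", time_s = c(0, 5, 9, 14),
#'   zone = c("arm0", "arm1", "arm2", "arm0")
#' )
#' events_to_turns(ev)$token # clockwise rotation: R R R
#' @export
events_to_turns <- function(events, geometry = maze_geometry()) {
  stopifnot(inherits(geometry, "maze_geometry"))
  req <- c("subject_id", "time_s", "zone")
  if (!all(req %in% names(events))) {
    parameter_error("events must have columns subject_id, time_s, zone")
  }
  allowed <- c(geometry$arms, geometry$centre)
  bad <- setdiff(unique(events$zone), allowed)
  if (length(bad) > 0) {
    data_error(sprintf("unknown zone label(s): %s", paste(bad, collapse = ", ")))
  }
  cw_token <- if (geometry$clockwise_is_right) "R" else "L"
  ccw_token <- if (geometry$clockwise_is_right) "L" else "R"

  code_one <- function(df) {
    t <- df$time_s
    z <- df$zone
    n_events <- length(z)
    # debounce: dwell is the time to the next record; last dwell is unknown
    # and treated as long enough
    if (geometry$debounce_s > 0 && n_events > 1) {
      dwell <- c(diff(t), Inf)
      keep <- dwell >= geometry$debounce_s
      t <- t[keep]
      z <- z[keep]
    }
    # collapse consecutive duplicates (keep first occurrence)
    if (length(z) > 1) {
      keep <- c(TRUE, z[-1] != z[-length(z)])
      t <- t[keep]
      z <- z[keep]
    }
    n_centre <- sum(z == geometry$centre)
    t <- t[z != geometry$centre]
    z <- z[z != geometry$centre]
    # same-arm re-entries (arm -> centre -> same arm) surface as adjacent
    # duplicates once the centre is removed; they complete no choice
    reent <- 0L
    if (length(z) > 1) {
      dup <- c(FALSE, z[-1] == z[-length(z)])
      reent <- sum(dup)
      t <- t[!dup]
      z <- z[!dup]
    }
    qc <- tibble::tibble(
      subject_id = df$subject_id[1], n_events = n_events,
      n_centre = n_centre, n_same_arm_reentries = reent,
      n_turns = max(0L, length(z) - 1L)
    )
    if (length(z) < 2) {
      return(list(
        turns = tibble::tibble(subject_id = character(), token = character(),
                               time_s = numeric()),
        qc = qc
      ))
    }
    idx <- match(z, geometry$arms)
    step <- (idx[-1] - idx[-length(idx)]) %% 3 # 1 = clockwise, 2 = ccw
    list(
      turns = tibble::tibble(
        subject_id = df$subject_id[1],
        token = ifelse(step == 1, cw_token, ccw_token),
        time_s = t[-1]
      ),
      qc = qc
    )
  }

  parts <- events |>
    dplyr::arrange(.data$subject_id, .data$time_s) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_split() |>
    lapply(code_one)
  out <- dplyr::bind_rows(lapply(parts, `[[`, "turns"))
  attr(out, "qc") <- dplyr::bind_rows(lapply(parts, `[[`, "qc"))
  out
}

#' Assign turns to session time bins
#'
#' Bins are half-open: a turn at time `t` falls in bin
#' `floor(t / bin_width_s)`, so `t = 600` with 600-s bins opens bin 1.  A turn
#' exactly at the session end is assigned to the last bin (the only closed
#' boundary); turns beyond the session length are a data error.
#'
#' @param turns Turn tibble from [events_to_turns()].
#' @param cfg A [session_config()].
#' @return `turns` with an integer `bin` column in `[0, n_bins)`.
#' @export
assign_bins <- function(turns, cfg = session_config()) {
  stopifnot(inherits(cfg, "session_config"))
  if (!all(c("subject_id", "time_s") %in% names(turns))) {
    parameter_error("turns must have columns subject_id and time_s")
  }
  over <- turns$time_s > cfg$session_length_s
  if (any(over)) {
    i <- which(over)
    data_error(sprintf(
      "%d turn(s) beyond session length (%g s); first: subject '%s' at %g s",
      length(i), cfg$session_length_s, turns$subject_id[i[1]],
      turns$time_s[i[1]]
    ))
  }
  n_bins <- as.integer(cfg$session_length_s / cfg$bin_width_s)
  turns$bin <- pmin(as.integer(floor(turns$time_s / cfg$bin_width_s)),
                    n_bins - 1L)
  turns
}

#' Encode a turn sequence as an arm-entry path
#'
#' Inverse of [events_to_turns()] for clean sequences: starting from
#' `start_arm`, each `R` moves to the clockwise neighbour and each `L` to the
#' counterclockwise neighbour (under the geometry's convention), producing the
#' event stream a tracker would log for that walk. Used by the simulator so
#' synthetic cohorts exercise the full pipeline including turn coding.
#'
#' @param turns Tibble with `subject_id`, `token`, `time_s` for one subject.
#' @param geometry A [maze_geometry()].
#' @param start_arm Arm occupied at time 0; defaults to the first arm label.
#' @return An event tibble (`subject_id`, `time_s`, `zone`) whose first row is
#'   the starting arm at time 0.
#' @export
turns_to_events <- function(turns, geometry = maze_geometry(),
                            start_arm = NULL) {
  stopifnot(inherits(geometry, "maze_geometry"))
  start_arm <- start_arm %||% geometry$arms[1]
  if (!start_arm %in% geometry$arms) parameter_error("unknown start_arm")
  if (length(unique(turns$subject_id)) > 1) {
    parameter_error("turns_to_events expects a single subject")
  }
  if (nrow(turns) == 0) {
    parameter_error("turns_to_events needs at least one turn")
  }
  cw <- if (geometry$clockwise_is_right) "R" else "L"
  step <- ifelse(turns$token == cw, 1L, -1L)
  idx0 <- match(start_arm, geometry$arms)
  idx <- ((idx0 - 1L + cumsum(c(0L, step))) %% 3L) + 1L
  tibble::tibble(
    subject_id = turns$subject_id[1],
    time_s = c(0, turns$time_s),
    zone = geometry$arms[idx]
  )
}
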