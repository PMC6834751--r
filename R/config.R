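#' Session configuration
#'
#' Bundles the session-level parameters shared across the Y-maze, avoidance
#' conditioning and novel tank analyses: session length and bin width for the
#' 1-h Y-maze recording scored in 10-min bins, the strict laterality threshold,
#' the engagement (minimum-turns) exclusion rule, the novel-tank dimensions and
#' the thresholds behind the immobility and thigmotaxis endpoints.
#'
#' Times are seconds from session start, 0-based; turns are assigned to
#' half-open bins `[k * bin_width_s, (k + 1) * bin_width_s)`.
#'
#' @param session_length_s Y-maze session length in seconds; must be an integer
#'   multiple of `bin_width_s`.
#' @param bin_width_s Width of the analysis time bins in seconds.
#' @param bias_threshold_pct Strict threshold (in percent, exclusive) above
#'   which a side bias classifies a subject as lateralized. Must lie in
#'   (50, 100).
#' @param min_turns_for_inclusion Subjects with fewer total turns are flagged as
#'   non-engaged and excluded from cohort summaries.
#' @param tank_length_cm,tank_height_cm,tank_width_cm Novel-tank dimensions in
#'   cm (length x height x width).
#' @param thigmotaxis_margin_cm Distance from any wall (top view) within which a
#'   sample counts as thigmotaxis.
#' @param immobility_speed_cms Speed threshold in cm/s below which a fish is
#'   considered immobile.
#' @param immobility_min_duration_s Minimum duration of a sub-threshold run for
#'   it to count toward immobility time.
#' @param random_seed Optional integer seed recorded in run manifests and used
#'   by the pipeline's simulation mode.
#'
#' @return An object of class `session_config` (a named list).
#' @examples
#' cfg <- session_config()
#' cfg$session_length_s / cfg$bin_width_s # 6 bins
#' @export
session_config <- function(session_length_s = 3600,
                           bin_width_s = 600,
                           bias_threshold_pct = 60,
                           min_turns_for_inclusion = 20,
                           tank_length_cm = 30,
                           tank_height_cm = 15,
                           tank_width_cm = 12,
                           thigmotaxis_margin_cm = 2.4,
                           immobility_speed_cms = 0.5,
                           immobility_min_duration_s = 2,
                           random_seed = NULL) {
  if (session_length_s <= 0 || bin_width_s <= 0) {
    parameter_error("session_length_s and bin_width_s must be positive")
  }
  if (session_length_s %% bin_width_s != 0) {
    parameter_error(sprintf(
      "session_length_s (%s) must be an integer multiple of bin_width_s (%s)",
      session_length_s, bin_width_s
    ))
  }
  if (bias_threshold_pct <= 50 || bias_threshold_pct >= 100) {
    parameter_error("bias_threshold_pct must lie strictly between 50 and 100")
  }
  if (min_turns_for_inclusion < 0) {
    parameter_error("min_turns_for_inclusion must be non-negative")
  }
  for (nm in c("tank_length_cm", "tank_height_cm", "tank_width_cm",
               "thigmotaxis_margin_cm")) {
    if (get(nm) <= 0) parameter_error(sprintf("%s must be positive", nm))
  }
  structure(
    list(
      session_length_s = session_length_s,
      bin_width_s = bin_width_s,
      bias_threshold_pct = bias_threshold_pct,
      min_turns_for_inclusion = min_turns_for_inclusion,
      tank_length_cm = tank_length_cm,
      tank_height_cm = tank_height_cm,
      tank_width_cm = tank_width_cm,
      thigmotaxis_margin_cm = thigmotaxis_margin_cm,
      immobility_speed_cms = immobility_speed_cms,
      immobility_min_duration_s = immobility_min_duration_s,
      random_seed = random_seed
    ),
    class = "session_config"
  )
}

#' Read a session configuration from a YAML file
#'
#' Keys mirror the arguments of [session_config()]; absent keys take their
#' defaults, unknown keys are an error so that typos do not silently fall back
#' to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `session_config` object.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) format_error(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(session_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    format_error(sprintf(
      "unknown configuration key(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  do.call(session_config, vals)
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, if (is.null(x[[nm]])) "NULL" else x[[nm]]))
  }
  invisible(x)
}

#' Y-maze geometry
#'
#' Describes a three-arm maze: the arm labels in circular order as seen from
#' above, the centre-zone label, and the convention mapping arm-to-arm
#' transitions to left/right turns.  With `clockwise_is_right = TRUE` a
#' transition from an arm to its clockwise neighbour codes `R`; flip the flag
#' to match rigs whose camera mirrors the maze.
#'
#' @param arms Character vector of exactly three distinct arm labels, in
#'   clockwise order viewed from above.
#' @param centre Label of the centre zone.
#' @param clockwise_is_right Logical; if `TRUE` (default) clockwise transitions
#'   code `R` and counterclockwise `L`, reversed otherwise.
#' @param debounce_s Minimum dwell time in seconds for a zone entry to count;
#'   0 (default) keeps every entry.
#'
#' @return An object of class `maze_geometry`.
#' @examples
#' geom <- maze_geometry()
#' geom$arms
#' @export
maze_geometry <- function(arms = c("arm0", "arm1", "arm2"),
                          centre = "centre",
                          clockwise_is_right = TRUE,
                          debounce_s = 0) {
  if (length(arms) != 3 || anyDuplicated(arms) || centre %in% arms) {
    parameter_error("a maze needs exactly three distinct arm labels plus a distinct centre label")
  }
  if (debounce_s < 0) parameter_error("debounce_s must be non-negative")
  structure(
    list(
      arms = as.character(arms),
      centre = as.character(centre),
      clockwise_is_right = isTRUE(clockwise_is_right),
      debounce_s = debounce_s
    ),
    class = "maze_geometry"
  )
}

#' Pavlovian avoidance conditioning schedule
#'
#' Encodes the phase structure of the avoidance assay: habituation with the two
#' base patterns alternating sides on a fixed cadence, a baseline preference
#' phase, a conditioning block of CS+ presentations each followed by a brief
#' shock (metadata only; the shock is not modelled) and an inter-trial interval
#' of the CS- pattern, and finally a probe in which CS+ and CS- are shown at
#' opposite ends of the tank, swapping sides halfway through.
#'
#' Phase windows are contiguous and half-open. The CS+ side alternates every
#' `side_switch_s` seconds from session start, through habituation and
#' baseline; during the probe the CS+ end starts at `probe_cs_first_side` and
#' flips after `probe_switch_s` seconds.
#'
#' @param habituation_s Habituation duration in seconds.
#' @param side_switch_s Cadence of the side alternation during habituation and
#'   baseline.
#' @param baseline_s Baseline preference phase duration.
#' @param n_trials Number of CS+/US pairings.
#' @param cs_s CS+ presentation duration per trial.
#' @param iti_s Inter-trial interval (CS- shown) per trial.
#' @param probe_s Probe duration.
#' @param probe_switch_s Time into the probe at which CS+ and CS- swap ends.
#' @param cs_plus Which base pattern is the CS+ (counterbalanced across
#'   subjects in the assay); metadata only.
#' @param cs_start_side Side (`"left"` or `"right"`) showing the CS+ pattern at
#'   session start.
#' @param probe_cs_first_side Side showing CS+ for the first half of the probe.
#' @param us_voltage_v,us_duration_ms Unconditioned stimulus parameters,
#'   recorded as metadata only.
#' @param tank_length_cm,tank_width_cm Conditioning tank footprint; the CS+
#'   "vicinity" is the CS+ half of the `tank_length_cm` axis, split at the
#'   midline.
#'
#' @return An object of class `conditioning_schedule` with a `phases` tibble
#'   (`phase`, `start_s`, `end_s`).
#' @examples
#' sched <- conditioning_schedule()
#' sched$phases
#' @export
conditioning_schedule <- function(habituation_s = 1800,
                                  side_switch_s = 300,
                                  baseline_s = 600,
                                  n_trials = 9,
                                  cs_s = 1.5,
                                  iti_s = 8.5,
                                  probe_s = 60,
                                  probe_switch_s = 30,
                                  cs_plus = c("check", "grey"),
                                  cs_start_side = c("left", "right"),
                                  probe_cs_first_side = c("left", "right"),
                                  us_voltage_v = 9,
                                  us_duration_ms = 80,
                                  tank_length_cm = 25,
                                  tank_width_cm = 15) {
  cs_plus <- match.arg(cs_plus)
  cs_start_side <- match.arg(cs_start_side)
  probe_cs_first_side <- match.arg(probe_cs_first_side)
  for (nm in c("habituation_s", "side_switch_s", "baseline_s", "cs_s", "iti_s",
               "probe_s", "probe_switch_s", "tank_length_cm", "tank_width_cm")) {
    if (get(nm) <= 0) parameter_error(sprintf("%s must be positive", nm))
  }
  if (n_trials < 1) parameter_error("n_trials must be at least 1")
  if (probe_switch_s >= probe_s) {
    parameter_error("probe_switch_s must fall inside the probe")
  }
  conditioning_s <- n_trials * (cs_s + iti_s)
  starts <- cumsum(c(0, habituation_s, baseline_s, conditioning_s))
  phases <- tibble::tibble(
    phase = c("habituation", "baseline", "conditioning", "probe"),
    start_s = starts,
    end_s = starts + c(habituation_s, baseline_s, conditioning_s, probe_s)
  )
  structure(
    list(
      habituation_s = habituation_s,
      side_switch_s = side_switch_s,
      baseline_s = baseline_s,
      n_trials = n_trials,
      cs_s = cs_s,
      iti_s = iti_s,
      probe_s = probe_s,
      probe_switch_s = probe_switch_s,
      cs_plus = cs_plus,
      cs_start_side = cs_start_side,
      probe_cs_first_side = probe_cs_first_side,
      us_voltage_v = us_voltage_v,
      us_duration_ms = us_duration_ms,
      tank_length_cm = tank_length_cm,
      tank_width_cm = tank_width_cm,
      phases = phases
    ),
    class = "conditioning_schedule"
  )
}

# Piecewise-constant CS+ side over a phase window, as segments
# (start_s, end_s, side). Used by preference_fraction() to split each
# occupancy interval at the scheduled side changes.
cs_side_segments <- function(schedule, phase = c("baseline", "probe")) {
  phase <- match.arg(phase)
  win <- schedule$phases[schedule$phases$phase == phase, ]
  flip <- function(s) ifelse(s == "left", "right", "left")
  if (phase == "probe") {
    sw <- win$start_s + schedule$probe_switch_s
    return(tibble::tibble(
      start_s = c(win$start_s, sw),
      end_s = c(sw, win$end_s),
      side = c(schedule$probe_cs_first_side,
               flip(schedule$probe_cs_first_side))
    ))
  }
  # alternation cadence anchored at session start
  k0 <- floor(win$start_s / schedule$side_switch_s)
  k1 <- ceiling(win$end_s / schedule$side_switch_s) - 1
  ks <- k0:k1
  tibble::tibble(
    start_s = pmax(ks * schedule$side_switch_s, win$start_s),
    end_s = pmin((ks + 1) * schedule$side_switch_s, win$end_s),
    side = ifelse(ks %% 2 == 0, schedule$cs_start_side,
                  flip(schedule$cs_start_side))
  )
}
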