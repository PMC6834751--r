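#' Read an arm-entry event log
#'
#' Reads a delimited log of maze zone entries (one row per entry) as exported
#' by an automated Y-maze tracker, validates it against the maze geometry and
#' returns a tidy event table. Column names are configurable because
#' acquisition systems differ in their export dialects.
#'
#' Timestamps must be non-decreasing within each subject in file order; a
#' violation is reported as a data error with the first offending row.  Zone
#' labels outside the geometry's label set are a format error.
#'
#' @param path Path to a CSV file.
#' @param geometry A [maze_geometry()] defining the admissible zone labels.
#' @param time_col,subject_col,zone_col Column names in the file.
#' @return A tibble with columns `subject_id`, `time_s`, `zone`, ordered by
#'   subject and time.
#' @seealso [write_arm_entries()], [events_to_turns()]
#' @export
read_arm_entries <- function(path,
                             geometry = maze_geometry(),
                             time_col = "time_s",
                             subject_col = "subject_id",
                             zone_col = "zone") {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(time_col, subject_col, zone_col)) {
    if (!col %in% names(df)) {
      format_error(sprintf("missing required column '%s' in %s", col, path))
    }
  }
  df <- tibble::tibble(
    subject_id = as.character(df[[subject_col]]),
    time_s = df[[time_col]],
    zone = as.character(df[[zone_col]]),
    .row = seq_len(nrow(df))
  )
  if (!is.numeric(df$time_s)) {
    format_error(sprintf("column '%s' must be numeric", time_col))
  }
  if (any(!is.finite(df$time_s)) || any(df$time_s < 0)) {
    data_error(sprintf(
      "non-finite or negative time at row %d",
      df$.row[which(!is.finite(df$time_s) | df$time_s < 0)[1]]
    ))
  }
  allowed <- c(geometry$arms, geometry$centre)
  bad <- !df$zone %in% allowed
  if (any(bad)) {
    format_error(sprintf(
      "unknown zone label '%s' at row %d (allowed: %s)",
      df$zone[which(bad)[1]], df$.row[which(bad)[1]],
      paste(allowed, collapse = ", ")
    ))
  }
  # monotonicity in file order, per subject
  viol <- df |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(.drop_t = .data$time_s - dplyr::lag(.data$time_s)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$.drop_t) & .data$.drop_t < 0)
  if (nrow(viol) > 0) {
    data_error(sprintf(
      "non-monotone timestamps for subject '%s' at row %d",
      viol$subject_id[1], viol$.row[1]
    ))
  }
  df |>
    dplyr::arrange(.data$subject_id, .data$time_s) |>
    dplyr::select("subject_id", "time_s", "zone")
}

#' Write an arm-entry event table
#'
#' Inverse of [read_arm_entries()]: numbers are serialized at full precision so
#' a write/read round trip recovers the event sequence exactly.
#'
#' @param events Tibble with columns `subject_id`, `time_s`, `zone`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_arm_entries <- function(events, path) {
  stopifnot(all(c("subject_id", "time_s", "zone") %in% names(events)))
  readr::write_csv(events[, c("subject_id", "time_s", "zone")], path)
  invisible(path)
}

#' Read a tracked trajectory log
#'
#' Reads a delimited log of timestamped 2-D positions from video tracking.
#' `view = "top"` logs carry (length, width) coordinates, `view = "front"`
#' logs carry (length, height).  Out-of-bounds samples are clipped to the tank
#' bounding box rather than dropped, so occupancy time is conserved; the number
#' of clipped samples is reported in the `n_clipped` attribute for QC.
#'
#' @param path Path to a CSV file.
#' @param view `"top"` or `"front"`; selects which tank dimensions bound the
#'   second coordinate.
#' @param cfg A [session_config()] providing the tank dimensions.
#' @param time_col,subject_col,u_col,v_col Column names in the file.
#' @return A tibble with columns `subject_id`, `time_s`, `u`, `v`, `view`,
#'   ordered by subject and time, with attribute `n_clipped`.
#' @export
read_trajectory <- function(path,
                            view = c("top", "front"),
                            cfg = session_config(),
                            time_col = "time_s",
                            subject_col = "subject_id",
                            u_col = "u",
                            v_col = "v") {
  view <- match.arg(view)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(time_col, subject_col, u_col, v_col)) {
    if (!col %in% names(df)) {
      format_error(sprintf("missing required column '%s' in %s", col, path))
    }
  }
  for (col in c(u_col, v_col)) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(x))))[1]
      format_error(sprintf(
        "non-numeric coordinate in column '%s' at row %d", col,
        if (is.na(bad)) 1L else bad
      ))
    }
    if (anyNA(x)) {
      format_error(sprintf(
        "missing coordinate in column '%s' at row %d", col, which(is.na(x))[1]
      ))
    }
  }
  out <- tibble::tibble(
    subject_id = as.character(df[[subject_col]]),
    time_s = df[[time_col]],
    u = df[[u_col]],
    v = df[[v_col]],
    view = view
  )
  v_max <- if (view == "top") cfg$tank_width_cm else cfg$tank_height_cm
  u_max <- cfg$tank_length_cm
  clipped <- out$u < 0 | out$u > u_max | out$v < 0 | out$v > v_max
  out$u <- pmin(pmax(out$u, 0), u_max)
  out$v <- pmin(pmax(out$v, 0), v_max)
  # strict monotonicity per subject
  viol <- out |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(.dt = .data$time_s - dplyr::lag(.data$time_s)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$.dt) & .data$.dt <= 0)
  if (nrow(viol) > 0) {
    data_error(sprintf(
      "timestamps not strictly increasing for subject '%s' at row %d",
      viol$subject_id[1], viol$.row[1]
    ))
  }
  out <- dplyr::arrange(out, .data$subject_id, .data$time_s)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Write result tables with a sidecar schema
#'
#' Writes each table of a named list as `<name>.csv` under `out_dir` (numbers
#' at full precision, so read-back recovers values exactly and a second write
#' is byte-identical), plus a `schema.json` sidecar documenting each table's
#' columns and types.  All tables are validated before anything is written, so
#' a bad table leaves no partial output.
#'
#' @param tables Named list of non-empty data frames.
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a character vector of the files written.
#' @export
write_results <- function(tables, out_dir) {
  if (!is.list(tables) || length(tables) == 0 || is.null(names(tables)) ||
      any(names(tables) == "")) {
    parameter_error("'tables' must be a non-empty named list of data frames")
  }
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!is.data.frame(tab)) {
      parameter_error(sprintf("table '%s' is not a data frame", nm))
    }
    if (nrow(tab) == 0) {
      parameter_error(sprintf("table '%s' is empty; nothing written", nm))
    }
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", out_dir),
                   class = "lateralize_io_error")
  }
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("output directory not writable: %s", out_dir),
          class = "lateralize_io_error")
  }
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(tables[[nm]]), f)
    files <- c(files, f)
  }
  schema <- lapply(tables, function(tab) {
    lapply(stats::setNames(names(tab), names(tab)),
           function(col) class(tab[[col]])[1])
  })
  sf <- file.path(out_dir, "schema.json")
  jsonlite::write_json(schema, sf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, sf))
}
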