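#' Side-bias percentage of a token vector
#'
#' The bias index: `100 * (turns to one side) / (total turns)`.  Left and
#' right percentages are complementary (they sum to 100).  An empty token
#' vector has no defined bias and returns `NA`, never 0.
#'
#' @param tokens Character vector over `"L"`/`"R"` (case-insensitive).
#' @param side Which side to score.
#' @return A percentage in `[0, 100]`, or `NA_real_` for zero tokens.
#' @examples
#' bias_percentage(c("R", "R", "R", "L"), "R") # 75
#' @export
bias_percentage <- function(tokens, side = c("R", "L")) {
  side <- match.arg(side)
  tokens <- toupper(tokens)
  bad <- setdiff(unique(tokens), c("L", "R"))
  if (length(bad) > 0) {
    data_error(sprintf("tokens outside {L, R}: %s", paste(bad, collapse = ", ")))
  }
  n <- length(tokens)
  if (n == 0) return(NA_real_)
  100 * sum(tokens == side) / n
}

#' Per-bin bias percentages
#'
#' Left/right bias in each time bin that contains at least one turn.  Bins
#' without turns are simply absent (and counted by [per_bin_consistency()]).
#'
#' @param turns Turn tibble with a `bin` column ([assign_bins()] is applied if
#'   it is missing).
#' @param cfg A [session_config()].
#' @return A tibble `subject_id`, `bin`, `n_turns`, `bias_L_pct`, `bias_R_pct`.
#' @export
per_bin_bias <- function(turns, cfg = session_config()) {
  if (!"bin" %in% names(turns)) turns <- assign_bins(turns, cfg)
  turns |>
    dplyr::group_by(.data$subject_id, .data$bin) |>
    dplyr::summarise(
      n_turns = dplyr::n(),
      bias_L_pct = bias_percentage(.data$token, "L"),
      bias_R_pct = bias_percentage(.data$token, "R"),
      .groups = "drop"
    )
}

#' Across-bin consistency of the side bias
#'
#' Mean and coefficient of variation of the per-bin bias percentages across
#' the bins that contain turns, per side — a measure of how stable a subject's
#' lateralization is over the session.  The CV is `100 * sample SD / mean`
#' (n - 1 denominator) and is missing when the mean is zero.  Fewer than two
#' usable bins leave all four statistics missing.
#'
#' @param turns Turn tibble (binned or not).
#' @param cfg A [session_config()].
#' @return A tibble `subject_id`, `n_bins_used`, `n_bins_empty`, `mean_L_pct`,
#'   `mean_R_pct`, `cv_L_pct`, `cv_R_pct`.
#' @export
per_bin_consistency <- function(turns, cfg = session_config()) {
  n_bins <- as.integer(cfg$session_length_s / cfg$bin_width_s)
  cv <- function(x) {
    m <- mean(x)
    if (m <= 0) NA_real_ else 100 * stats::sd(x) / m
  }
  per_bin_bias(turns, cfg) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_bins_used = dplyr::n(),
      n_bins_empty = n_bins - dplyr::n(),
      mean_L_pct = if (dplyr::n() >= 2) mean(.data$bias_L_pct) else NA_real_,
      mean_R_pct = if (dplyr::n() >= 2) mean(.data$bias_R_pct) else NA_real_,
      cv_L_pct = if (dplyr::n() >= 2) cv(.data$bias_L_pct) else NA_real_,
      cv_R_pct = if (dplyr::n() >= 2) cv(.data$bias_R_pct) else NA_real_,
      .groups = "drop"
    )
}

#' Three-way laterality classification
#'
#' A subject is `right_biased` if its whole-session right-turn percentage
#' strictly exceeds the threshold, `left_biased` if the left percentage does,
#' and `non_biased` otherwise.  The threshold is strict: a bias of exactly the
#' threshold is non-biased.  Undefined bias (no turns) yields `NA`.
#'
#' @param bias_L_pct,bias_R_pct Numeric vectors of complementary side
#'   percentages.
#' @param threshold_pct Strict threshold, default 60.
#' @return Character vector over
#'   `c("left_biased", "right_biased", "non_biased")`.
#' @examples
#' classify_laterality(40, 60) # exactly at threshold: non_biased
#' classify_laterality(39.9, 60.1) # right_biased
#' @export
classify_laterality <- function(bias_L_pct, bias_R_pct, threshold_pct = 60) {
  if (threshold_pct <= 50 || threshold_pct >= 100) {
    parameter_error("threshold_pct must lie strictly between 50 and 100")
  }
  dplyr::case_when(
    is.na(bias_L_pct) | is.na(bias_R_pct) ~ NA_character_,
    bias_R_pct > threshold_pct ~ "right_biased",
    bias_L_pct > threshold_pct ~ "left_biased",
    TRUE ~ "non_biased"
  )
}

laterality_levels <- c("left_biased", "right_biased", "non_biased")

#' Per-subject laterality results
#'
#' The full laterality scoring for each subject: whole-session left/right bias
#' percentages, per-bin consistency (mean and CV per side), the strict
#' three-way class label based on the whole-session bias, and the engagement
#' flag (`included = FALSE` for subjects with fewer than
#' `cfg$min_turns_for_inclusion` turns, mirroring non-engagement screening).
#'
#' @param turns Turn tibble from [events_to_turns()].
#' @param cfg A [session_config()].
#' @param subjects Optional character vector of all subjects in the session;
#'   subjects absent from `turns` (zero turns) are then reported with missing
#'   bias, missing label and `included = FALSE`.
#' @return A tibble with one row per subject: `subject_id`, `n_turns`,
#'   `bias_L_pct`, `bias_R_pct`, `n_bins_used`, `n_bins_empty`, `mean_L_pct`,
#'   `mean_R_pct`, `cv_L_pct`, `cv_R_pct`, `label`, `included`.
#' @export
subject_laterality <- function(turns, cfg = session_config(), subjects = NULL) {
  stopifnot(inherits(cfg, "session_config"))
  overall <- turns |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_turns = dplyr::n(),
      bias_L_pct = bias_percentage(.data$token, "L"),
      bias_R_pct = bias_percentage(.data$token, "R"),
      .groups = "drop"
    )
  if (!is.null(subjects)) {
    missing_ids <- setdiff(as.character(subjects), overall$subject_id)
    if (length(missing_ids) > 0) {
      overall <- dplyr::bind_rows(
        overall,
        tibble::tibble(
          subject_id = missing_ids, n_turns = 0L,
          bias_L_pct = NA_real_, bias_R_pct = NA_real_
        )
      )
    }
  }
  cons <- if (nrow(turns) > 0) {
    per_bin_consistency(turns, cfg)
  } else {
    tibble::tibble(
      subject_id = character(), n_bins_used = integer(),
      n_bins_empty = integer(), mean_L_pct = numeric(),
      mean_R_pct = numeric(), cv_L_pct = numeric(), cv_R_pct = numeric()
    )
  }
  overall |>
    dplyr::left_join(cons, by = "subject_id") |>
    dplyr::mutate(
      label = classify_laterality(.data$bias_L_pct, .data$bias_R_pct,
                                  cfg$bias_threshold_pct),
      included = .data$n_turns >= cfg$min_turns_for_inclusion &
        !is.na(.data$label)
    ) |>
    dplyr::arrange(.data$subject_id)
}

#' Cohort-level class summary
#'
#' Counts and percentages of the three laterality classes over the included
#' subjects.
#'
#' @param results Per-subject laterality tibble (needs `label` and `included`
#'   columns), e.g. from [subject_laterality()].
#' @return A tibble `label`, `n`, `pct` covering all three classes (zero
#'   counts kept).
#' @examples
#' res <- tibble::tibble(
#'   label = rep(c("non_biased", "left_biased", "right_biased"), c(47, 28, 28)),
#'   included = TRUE
#' )
#' cohort_class_summary(res) # 45.63 / 27.18 / 27.18 %
#' @export
cohort_class_summary <- function(results) {
  if (!all(c("label", "included") %in% names(results))) {
    parameter_error("results must have columns label and included")
  }
  res <- dplyr::filter(results, .data$included)
  if (nrow(res) == 0) {
    data_error("no included subjects; cannot summarise cohort classes")
  }
  counts <- table(factor(res$label, levels = laterality_levels))
  tibble::tibble(
    label = laterality_levels,
    n = as.integer(counts),
    pct = 100 * as.integer(counts) / nrow(res)
  )
}
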