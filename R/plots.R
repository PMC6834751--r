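#' Plot a tetragram profile
#'
#' Bar chart of mean relative frequency per tetragram word, optionally split
#' by laterality class — the standard way to eyeball the search-strategy
#' signature (alternation peaks at `lrlr`/`rlrl`, perseveration at
#' `llll`/`rrrr`).
#'
#' @param profile Long tetragram tibble from [count_tetragrams()].
#' @param labels Optional tibble `subject_id`, `label` (e.g. from
#'   [subject_laterality()]) to facet the profile by class.
#' @return A ggplot object.
#' @export
plot_tetragram_profile <- function(profile, labels = NULL) {
  df <- profile
  if (!is.null(labels)) {
    df <- dplyr::inner_join(df, dplyr::select(labels, "subject_id", "label"),
                            by = "subject_id")
  } else {
    df$label <- "all"
  }
  df <- df |>
    dplyr::filter(!is.na(.data$rel_freq)) |>
    dplyr::group_by(.data$label, .data$word) |>
    dplyr::summarise(
      mean_freq = mean(.data$rel_freq),
      sem = if (dplyr::n() >= 2) {
        stats::sd(.data$rel_freq) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(word = factor(.data$word, levels = tetragram_words()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$word, y = .data$mean_freq)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_freq - .data$sem,
                   ymax = .data$mean_freq + .data$sem),
      width = 0.3, na.rm = TRUE
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$label)) +
    ggplot2::labs(x = "tetragram", y = "mean relative frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-bin bias time courses
#'
#' One line per subject of the right-turn percentage across session bins, with
#' the lateralization threshold band marked — shows at a glance whether a
#' subject's bias is consistent across the hour.
#'
#' @param turns Turn tibble (binned or not).
#' @param cfg A [session_config()].
#' @return A ggplot object.
#' @export
plot_bias_timecourse <- function(turns, cfg = session_config()) {
  df <- per_bin_bias(turns, cfg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$bias_R_pct,
                                   group = .data$subject_id)) +
    ggplot2::geom_hline(yintercept = c(cfg$bias_threshold_pct,
                                       100 - cfg$bias_threshold_pct),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "time bin", y = "right-turn bias (%)") +
    ggplot2::theme_minimal()
}

#' @rdname permutation_test
#' @param object A `perm_test` object.
#' @param ... Unused.
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "|mean difference| under label shuffling",
      y = "count",
      title = sprintf("observed = %.3g, p = %.3g", object$observed,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}
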