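#' Per-class descriptive summary
#'
#' Mean and standard error of the mean (sample SD / sqrt(n)) of each metric,
#' per group.  Groups with a single subject report a missing SEM; groups with
#' no non-missing values for a metric are dropped with a warning.
#'
#' @param data Data frame with one row per subject.
#' @param group Column (tidy-select) holding the group label.
#' @param ... Tidy-selection of metric columns; defaults to every numeric
#'   column other than the group.
#' @return A tibble `group`, `metric`, `n`, `mean`, `sem`.
#' @examples
#' df <- tibble::tibble(label = c("a", "a", "a", "b"), x = c(1, 2, 3, 5))
#' group_summary(df, label) # mean 2, sem sd(1:3)/sqrt(3); b: sem NA
#' @export
group_summary <- function(data, group, ...) {
  group <- rlang::enquo(group)
  dots <- rlang::enquos(...)
  metric_cols <- if (length(dots) == 0) {
    setdiff(names(dplyr::select(data, dplyr::where(is.numeric))),
            names(dplyr::select(data, !!group)))
  } else {
    names(dplyr::select(data, !!!dots))
  }
  if (length(metric_cols) == 0) parameter_error("no metric columns selected")
  long <- data |>
    dplyr::select(group = !!group, dplyr::all_of(metric_cols)) |>
    tidyr::pivot_longer(-"group", names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  empty <- setdiff(
    as.vector(outer(unique(dplyr::pull(data, !!group)), metric_cols, paste)),
    paste(long$group, long$metric)
  )
  if (length(empty) > 0) {
    warn(sprintf("dropping group/metric pairs with no data: %s",
                 paste(empty, collapse = "; ")))
  }
  long |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = if (dplyr::n() >= 2) {
        stats::sd(.data$value) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Two-group permutation test
#'
#' Label-shuffle test of the absolute difference of group means: the observed
#' statistic is compared with its distribution under `n_perm` random
#' reassignments of the group labels, and the two-sided p-value is
#' `(1 + #(null >= observed)) / (n_perm + 1)` — valid (conservative) under
#' exchangeability and never smaller than `1 / (n_perm + 1)`.
#'
#' @param data Data frame.
#' @param value Column (tidy-select) of the response.
#' @param group Column (tidy-select) of the group label; exactly two groups,
#'   each with at least two observations.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return An object of class `perm_test` with [tidy()], [glance()],
#'   [autoplot()] and print methods.
#' @examples
#' df <- tibble::tibble(g = rep(c("x", "y"), each = 4), v = c(1:4, 3:6))
#' pt <- permutation_test(df, v, g, n_perm = 199, seed = 1)
#' tidy(pt)
#' @export
permutation_test <- function(data, value, group, n_perm = 999, seed = NULL) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  levels <- unique(g)
  if (length(levels) != 2) {
    parameter_error("permutation_test requires exactly two groups")
  }
  n1 <- sum(g == levels[1])
  n2 <- sum(g == levels[2])
  if (n1 < 2 || n2 < 2) {
    parameter_error("each group needs at least two observations")
  }
  if (n_perm < 1) parameter_error("n_perm must be at least 1")
  observed <- abs(mean(v[g == levels[1]]) - mean(v[g == levels[2]]))
  n <- length(v)
  null <- maybe_with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, n1)
      abs(mean(v[idx]) - mean(v[-idx]))
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed - 1e-12)) / (n_perm + 1)
  structure(
    list(
      observed = observed, null = null, p_value = p, n_perm = n_perm,
      groups = levels, n = c(n1, n2), seed = seed
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Two-group permutation test (absolute mean difference)\n")
  cat(sprintf("  groups: %s (n = %d) vs %s (n = %d)\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2]))
  cat(sprintf("  observed |diff| = %.4g\n", x$observed))
  cat(sprintf("  p = %.4g  (%d permutations)\n", x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `perm_test` object.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    group1 = x$groups[1], group2 = x$groups[2],
    estimate = x$observed, p.value = x$p_value, n.perm = x$n_perm
  )
}

#' @rdname permutation_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$observed, p.value = x$p_value, n.perm = x$n_perm,
    n1 = x$n[1], n2 = x$n[2]
  )
}

#' Pairwise permutation contrasts over several metrics
#'
#' Runs [permutation_test()] for every metric and every pair of group levels,
#' optionally adjusting p-values across the whole table
#' (Benjamini-Hochberg); the default reports unadjusted per-test p-values,
#' making the multiplicity choice explicit.
#'
#' @param data Data frame with one row per subject.
#' @param group Column (tidy-select) holding the group label.
#' @param ... Tidy-selection of metric columns (default: all numeric).
#' @param n_perm Permutations per test.
#' @param seed Optional integer seed; per-test seeds are derived from it.
#' @param p_adjust `"none"` or `"BH"`.
#' @return A tibble `metric`, `group1`, `group2`, `n1`, `n2`, `estimate`,
#'   `p.value` (and `p.adjusted` unless `p_adjust = "none"`).
#' @export
group_contrasts <- function(data, group, ..., n_perm = 999, seed = NULL,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  group <- rlang::enquo(group)
  dots <- rlang::enquos(...)
  metric_cols <- if (length(dots) == 0) {
    setdiff(names(dplyr::select(data, dplyr::where(is.numeric))),
            names(dplyr::select(data, !!group)))
  } else {
    names(dplyr::select(data, !!!dots))
  }
  g <- as.character(dplyr::pull(data, !!group))
  levels <- unique(g[!is.na(g)])
  if (length(levels) < 2) parameter_error("need at least two groups")
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  counter <- 0
  rows <- purrr::map(metric_cols, function(m) {
    purrr::map(pairs, function(pr) {
      counter <<- counter + 1
      sub <- tibble::tibble(value = data[[m]][g %in% pr], group = g[g %in% pr])
      pt <- permutation_test(
        sub, "value", "group", n_perm = n_perm,
        seed = if (is.null(seed)) NULL else seed + counter
      )
      tibble::tibble(
        metric = m, group1 = pr[1], group2 = pr[2],
        n1 = pt$n[1], n2 = pt$n[2],
        estimate = pt$observed, p.value = pt$p_value
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (p_adjust != "none") {
    rows$p.adjusted <- stats::p.adjust(rows$p.value, method = p_adjust)
  }
  rows
}
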