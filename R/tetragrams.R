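#' The sixteen tetragram words
#'
#' All length-4 words over the alphabet \{l, r\}, in binary order with `l`
#' before `r`: `llll`, `lllr`, `llrl`, ..., `rrrr`.
#'
#' @return Character vector of length 16.
#' @export
tetragram_words <- function() {
  grid <- expand.grid(
    c4 = c("l", "r"), c3 = c("l", "r"), c2 = c("l", "r"), c1 = c("l", "r"),
    stringsAsFactors = FALSE
  )
  paste0(grid$c1, grid$c2, grid$c3, grid$c4)
}

sliding_words <- function(tokens) {
  n <- length(tokens)
  if (n < 4) return(character(0))
  s <- paste(tolower(tokens), collapse = "")
  substring(s, 1:(n - 3), 4:n)
}

#' Tetragram profile of a turn sequence
#'
#' Slides a window of four consecutive choices (stride 1) over each subject's
#' whole-session turn stream and tallies the 16 possible words.  Relative
#' frequencies are taken over the number of windows, `n_turns - 3`, so they
#' sum to 1; sequences shorter than 4 turns yield zero counts and missing
#' relative frequencies.
#'
#' With `by_bin = TRUE` each window is assigned to the time bin of its final
#' (fourth) turn — a window completes at its fourth choice — and counts and
#' relative frequencies are tallied per bin; `turns` must then carry a `bin`
#' column (see [assign_bins()]).
#'
#' @param turns Turn tibble (`subject_id`, `token`, `time_s`, optionally
#'   `bin`).
#' @param by_bin Tally per time bin instead of over the whole session.
#' @return A tibble with one row per subject (and bin) per word:
#'   `subject_id`, (`bin`,) `word`, `count`, `rel_freq`.
#' @examples
#' turns <- tibble::tibble(
#'   subject_id = "f1", token = c("L", "R", "L", "R", "L", "R"),
#'   time_s = 1:6
#' )
#' prof <- count_tetragrams(turns)
#' prof[prof$count > 0, ] # lrlr x2, rlrl x1
#' @export
count_tetragrams <- function(turns, by_bin = FALSE) {
  if (!all(c("subject_id", "token") %in% names(turns))) {
    parameter_error("turns must have columns subject_id and token")
  }
  if (by_bin && !"bin" %in% names(turns)) {
    parameter_error("by_bin = TRUE requires a 'bin' column; see assign_bins()")
  }
  words <- tetragram_words()
  one <- function(df) {
    w <- sliding_words(df$token)
    if (by_bin) {
      bins <- df$bin[seq_along(w) + 3L] # bin of the window's final turn
      tab <- as.data.frame(table(
        bin = factor(bins, levels = sort(unique(df$bin))),
        word = factor(w, levels = words)
      ), stringsAsFactors = FALSE)
      out <- tibble::tibble(
        subject_id = df$subject_id[1],
        bin = as.integer(as.character(tab$bin)),
        word = tab$word,
        count = as.integer(tab$Freq)
      )
      out |>
        dplyr::group_by(.data$bin) |>
        dplyr::mutate(rel_freq = if (sum(.data$count) > 0) {
          .data$count / sum(.data$count)
        } else {
          NA_real_
        }) |>
        dplyr::ungroup()
    } else {
      counts <- as.integer(table(factor(w, levels = words)))
      tibble::tibble(
        subject_id = df$subject_id[1],
        word = words,
        count = counts,
        rel_freq = if (length(w) > 0) counts / length(w) else NA_real_
      )
    }
  }
  turns |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_split() |>
    lapply(one) |>
    dplyr::bind_rows()
}

#' Search-strategy scores from tetragrams
#'
#' Per-subject summary of the tetragram profile: total turns, number of
#' overlapping windows (`max(0, n_turns - 3)`), the alternation score (relative
#' frequency of `lrlr` + `rlrl`, a working-memory-like strategy) and the
#' repetition score (`llll` + `rrrr`, perseverative responding).  Scores are
#' missing when fewer than four turns were made.
#'
#' @param turns Turn tibble (`subject_id`, `token`, ...).
#' @return A tibble with columns `subject_id`, `n_turns`, `n_tetragrams`,
#'   `alternation_score`, `repetition_score`.
#' @export
tetragram_scores <- function(turns) {
  one <- function(df) {
    w <- sliding_words(df$token)
    n_tet <- length(w)
    tibble::tibble(
      subject_id = df$subject_id[1],
      n_turns = nrow(df),
      n_tetragrams = n_tet,
      alternation_score = if (n_tet > 0) {
        sum(w %in% c("lrlr", "rlrl")) / n_tet
      } else {
        NA_real_
      },
      repetition_score = if (n_tet > 0) {
        sum(w %in% c("llll", "rrrr")) / n_tet
      } else {
        NA_real_
      }
    )
  }
  turns |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_split() |>
    lapply(one) |>
    dplyr::bind_rows()
}
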