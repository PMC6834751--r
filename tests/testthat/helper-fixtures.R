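# Shared fixtures and independent oracles, built in code.

make_events <- function(zones, subject = "f1", t0 = 0, dt = 5) {
  tibble::tibble(
    subject_id = subject,
    time_s = t0 + dt * (seq_along(zones) - 1),
    zone = zones
  )
}

make_turns <- function(tokens, subject = "f1", times = NULL) {
  tibble::tibble(
    subject_id = subject,
    token = toupper(tokens),
    time_s = times %||% seq_along(tokens)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent brute-force oracle for the expected tetragram frequencies of the
# first-order chain: enumerate every length-6 token path, weight it by its
# stationary probability, and average the word counts over the path's three
# overlapping windows.  Exercises stationarity and window-averaging rather
# than the single-window product formula.
enum_tetragram_freqs <- function(a, b) {
  pi_r <- a / (a + 1 - b)
  P <- matrix(c(1 - a, a, 1 - b, b), nrow = 2, byrow = TRUE,
              dimnames = list(c("l", "r"), c("l", "r")))
  words <- tetragram_words()
  acc <- stats::setNames(numeric(16), words)
  grid <- expand.grid(rep(list(c("l", "r")), 6), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    s <- unlist(grid[i, ], use.names = FALSE)
    p <- if (s[1] == "r") pi_r else 1 - pi_r
    for (k in 1:5) p <- p * P[s[k], s[k + 1]]
    str <- paste(s, collapse = "")
    for (w in substring(str, 1:3, 4:6)) acc[w] <- acc[w] + p / 3
  }
  acc
}
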