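#' First-order Markov turn-model parameters
#'
#' The minimal generative model for a left/right choice stream that can
#' express both a marginal side bias and the alternation/repetition axis:
#' a two-state Markov chain with `a = P(next = R | prev = L)` and
#' `b = P(next = R | prev = R)`.  `a = b` recovers an i.i.d. Bernoulli(`a`)
#' stream; `a > b` favours alternation, `a < b` perseveration.  Turn times
#' follow a constant-rate exponential inter-turn process truncated at the
#' session length.
#'
#' @param a Probability of turning right after a left turn, in `[0, 1]`.
#' @param b Probability of turning right after a right turn, in `[0, 1]`.
#' @param initial_R_prob Probability that the first turn is `R`; defaults to
#'   the stationary right-turn probability `a / (a + 1 - b)` (0.5 when the
#'   chain has no stationary law).
#' @param turn_rate_per_min Expected turns per minute; must be positive.
#' @param session_length_s Session length in seconds.
#' @return An object of class `turn_model_params`.
#' @examples
#' p <- turn_model_params(a = 0.6, b = 0.7)
#' stationary_R(p$a, p$b) # 2/3
#' @export
turn_model_params <- function(a, b, initial_R_prob = NULL,
                              turn_rate_per_min = 3,
                              session_length_s = 3600) {
  for (x in list(a = a, b = b)) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      parameter_error("a and b must be probabilities in [0, 1]")
    }
  }
  if (turn_rate_per_min <= 0) {
    parameter_error("turn_rate_per_min must be positive")
  }
  if (session_length_s <= 0) {
    parameter_error("session_length_s must be positive")
  }
  if (is.null(initial_R_prob)) {
    pi_r <- stationary_R(a, b)
    initial_R_prob <- if (is.na(pi_r)) 0.5 else pi_r
  }
  if (initial_R_prob < 0 || initial_R_prob > 1) {
    parameter_error("initial_R_prob must lie in [0, 1]")
  }
  structure(
    list(
      a = a, b = b, initial_R_prob = initial_R_prob,
      turn_rate_per_min = turn_rate_per_min,
      session_length_s = session_length_s
    ),
    class = "turn_model_params"
  )
}

#' Stationary right-turn probability of the turn model
#'
#' `P(R) = a / (a + 1 - b)` when `a + 1 - b > 0`; `NA` for the degenerate
#' chain (`a = 0`, `b = 1`) whose stationary law is not unique.
#'
#' @param a,b Transition probabilities as in [turn_model_params()].
#' @return A probability, or `NA_real_`.
#' @export
stationary_R <- function(a, b) {
  denom <- a + 1 - b
  if (denom <= 0) NA_real_ else a / denom
}

#' Simulate a Markov token stream
#'
#' Draws `n` tokens from the first-order chain.  The low-level primitive
#' behind [simulate_turn_sequence()]; useful on its own for fixed-length
#' experiments such as transition-probability recovery.
#'
#' @param n Number of tokens.
#' @param a,b Transition probabilities.
#' @param initial_R_prob Probability the first token is `R`; defaults to the
#'   stationary probability (0.5 if degenerate).
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return Character vector of `"L"`/`"R"` of length `n`.
#' @export
simulate_tokens <- function(n, a, b, initial_R_prob = NULL, seed = NULL) {
  if (n < 0) parameter_error("n must be non-negative")
  if (is.null(initial_R_prob)) {
    pi_r <- stationary_R(a, b)
    initial_R_prob <- if (is.na(pi_r)) 0.5 else pi_r
  }
  if (n == 0) return(character(0))
  maybe_with_seed(seed, {
    u <- runif(n)
    x <- logical(n)
    x[1] <- u[1] < initial_R_prob
    if (n > 1) {
      for (i in 2:n) {
        x[i] <- u[i] < (if (x[i - 1]) b else a)
      }
    }
    ifelse(x, "R", "L")
  })
}

#' Estimate turn-model parameters from a token stream
#'
#' Conditional-frequency estimates: `a_hat` is the fraction of transitions out
#' of `L` that land on `R`, `b_hat` likewise out of `R`.
#'
#' @param tokens Character vector over `"L"`/`"R"`.
#' @return A tibble `a_hat`, `b_hat`, `n_from_L`, `n_from_R`.
#' @export
estimate_turn_model <- function(tokens) {
  tokens <- toupper(tokens)
  n <- length(tokens)
  if (n < 2) {
    return(tibble::tibble(a_hat = NA_real_, b_hat = NA_real_,
                          n_from_L = 0L, n_from_R = 0L))
  }
  prev <- tokens[-n]
  nxt <- tokens[-1]
  n_from_L <- sum(prev == "L")
  n_from_R <- sum(prev == "R")
  tibble::tibble(
    a_hat = if (n_from_L > 0) sum(prev == "L" & nxt == "R") / n_from_L else NA_real_,
    b_hat = if (n_from_R > 0) sum(prev == "R" & nxt == "R") / n_from_R else NA_real_,
    n_from_L = n_from_L,
    n_from_R = n_from_R
  )
}

#' Simulate one subject's Y-maze session
#'
#' Draws turn times from the exponential inter-turn process truncated at the
#' session length and tokens from the Markov chain, then encodes the sequence
#' as the arm-entry path a tracker would log (via [turns_to_events()]), so
#' synthetic data exercise the full pipeline including turn coding.
#'
#' @param params A [turn_model_params()].
#' @param seed Optional integer seed.
#' @param subject_id Subject label.
#' @param geometry A [maze_geometry()] for the arm-path encoding.
#' @param start_arm Arm occupied at time 0 (default: first arm label).
#' @return A list with elements `turns` (tibble `subject_id`, `token`,
#'   `time_s`), `events` (arm-entry tibble) and `params`.
#' @examples
#' sim <- simulate_turn_sequence(turn_model_params(1, 1), seed = 1)
#' unique(sim$turns$token) # absorbing all-R chain
#' @export
simulate_turn_sequence <- function(params, seed = NULL, subject_id = "f01",
                                   geometry = maze_geometry(),
                                   start_arm = NULL) {
  stopifnot(inherits(params, "turn_model_params"))
  maybe_with_seed(seed, {
    rate_s <- params$turn_rate_per_min / 60
    times <- numeric(0)
    last <- 0
    repeat {
      chunk <- cumsum(rexp(256, rate_s)) + last
      times <- c(times, chunk)
      last <- times[length(times)]
      if (last > params$session_length_s) break
    }
    times <- times[times <= params$session_length_s]
    n <- length(times)
    tokens <- simulate_tokens(n, params$a, params$b, params$initial_R_prob)
    turns <- tibble::tibble(subject_id = subject_id, token = tokens,
                            time_s = times)
    events <- if (n > 0) {
      turns_to_events(turns, geometry, start_arm)
    } else {
      tibble::tibble(subject_id = subject_id, time_s = 0,
                     zone = start_arm %||% geometry$arms[1])
    }
    list(turns = turns, events = events, params = params)
  })
}

#' Expected tetragram frequencies under the turn model
#'
#' Closed-form oracle: for a word `w1 w2 w3 w4` the expected relative
#' frequency of overlapping windows equals the stationary word probability
#' `pi(w1) * P(w2|w1) * P(w3|w2) * P(w4|w3)`.  The 16 values sum to 1.  For
#' the fair i.i.d. chain every word has probability 1/16; for the degenerate
#' chain without a unique stationary law (`a = 0`, `b = 1`) all values are
#' `NA` with a warning.
#'
#' @param a,b Transition probabilities as in [turn_model_params()].
#' @return A tibble `word`, `freq` over the 16 words of [tetragram_words()].
#' @examples
#' expected_tetragram_freqs(0.5, 0.5)$freq # all 1/16
#' @export
expected_tetragram_freqs <- function(a, b) {
  words <- tetragram_words()
  pi_r <- stationary_R(a, b)
  if (is.na(pi_r)) {
    warn("chain has no unique stationary law (a = 0, b = 1); frequencies undefined")
    return(tibble::tibble(word = words, freq = NA_real_))
  }
  P <- matrix(c(1 - a, a, 1 - b, b), nrow = 2, byrow = TRUE,
              dimnames = list(c("l", "r"), c("l", "r")))
  pi0 <- c(l = 1 - pi_r, r = pi_r)
  freq <- vapply(words, function(w) {
    ch <- strsplit(w, "")[[1]]
    p <- pi0[[ch[1]]]
    for (k in 1:3) p <- p * P[ch[k], ch[k + 1]]
    p
  }, numeric(1))
  tibble::tibble(word = words, freq = unname(freq))
}

#' Cohort simulation design
#'
#' Class sizes and per-class turn-model parameter distributions for a
#' simulated screening cohort.  Defaults are a 28 left- / 28 right- / 47
#' non-biased cohort; non-biased fish are alternation-dominant with no
#' marginal bias (`a = 0.65`, `b = 0.35`), lateralized fish carry an i.i.d.
#' side bias (`a = b = 0.72` right, mirrored left) that also raises their
#' repetition score and lowers alternation, and right-biased fish turn at a
#' lower rate (2.4 vs 3 turns/min).  Per-fish parameters jitter uniformly
#' around the class values.
#'
#' @param n_left,n_right,n_non Class sizes.
#' @param class_params Named list (`left`, `right`, `non`) of lists with
#'   elements `a`, `b`, `rate` (turns/min).
#' @param jitter_ab Half-width of the uniform per-fish jitter on `a` and `b`.
#' @param jitter_rate Relative half-width of the uniform jitter on the turn
#'   rate.
#' @param session_length_s Session length.
#' @param random_seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_left = 28, n_right = 28, n_non = 47,
                        class_params = list(
                          non = list(a = 0.65, b = 0.35, rate = 3),
                          left = list(a = 0.28, b = 0.28, rate = 3),
                          right = list(a = 0.72, b = 0.72, rate = 2.4)
                        ),
                        jitter_ab = 0.03,
                        jitter_rate = 0.15,
                        session_length_s = 3600,
                        random_seed = 1) {
  if (n_left < 0 || n_right < 0 || n_non < 0 ||
      n_left + n_right + n_non == 0) {
    parameter_error("class sizes must be non-negative with a positive total")
  }
  if (!all(c("non", "left", "right") %in% names(class_params))) {
    parameter_error("class_params must name 'non', 'left' and 'right'")
  }
  structure(
    list(
      n_left = n_left, n_right = n_right, n_non = n_non,
      class_params = class_params, jitter_ab = jitter_ab,
      jitter_rate = jitter_rate, session_length_s = session_length_s,
      random_seed = random_seed
    ),
    class = "cohort_spec"
  )
}

#' Simulate a screening cohort with ground truth
#'
#' Draws per-fish parameters from the cohort design, simulates each session
#' and pools the arm-entry events, turn sequences and a ground-truth table
#' recording each fish's true class and parameters for recovery experiments.
#' Deterministic given the spec's `random_seed`: the same spec yields
#' identical output.
#'
#' @param spec A [cohort_spec()].
#' @param geometry A [maze_geometry()].
#' @return A list with `events`, `turns`, `truth` (tibble `subject_id`,
#'   `class`, `a`, `b`, `turn_rate_per_min`) and `spec`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_left = 1, n_right = 1, n_non = 1))
#' sim$truth
#' @export
simulate_cohort <- function(spec = cohort_spec(), geometry = maze_geometry()) {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- rep(c("left_biased", "right_biased", "non_biased"),
                 c(spec$n_left, spec$n_right, spec$n_non))
  key <- c(left_biased = "left", right_biased = "right", non_biased = "non")
  maybe_with_seed(spec$random_seed, {
    sims <- purrr::imap(classes, function(cls, i) {
      cp <- spec$class_params[[key[[cls]]]]
      a <- min(max(cp$a + runif(1, -spec$jitter_ab, spec$jitter_ab), 0.01), 0.99)
      b <- min(max(cp$b + runif(1, -spec$jitter_ab, spec$jitter_ab), 0.01), 0.99)
      rate <- cp$rate * runif(1, 1 - spec$jitter_rate, 1 + spec$jitter_rate)
      params <- turn_model_params(
        a = a, b = b, turn_rate_per_min = rate,
        session_length_s = spec$session_length_s
      )
      sim <- simulate_turn_sequence(
        params, subject_id = sprintf("f%03d", i), geometry = geometry,
        start_arm = sample(geometry$arms, 1)
      )
      sim$truth <- tibble::tibble(
        subject_id = sprintf("f%03d", i), class = cls,
        a = a, b = b, turn_rate_per_min = rate
      )
      sim
    })
    list(
      events = dplyr::bind_rows(purrr::map(sims, "events")),
      turns = dplyr::bind_rows(purrr::map(sims, "turns")),
      truth = dplyr::bind_rows(purrr::map(sims, "truth")),
      spec = spec
    )
  })
}

# Reflect a coordinate into [lo, hi] by folding at the walls.
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  y + lo
}

#' Simulate a novel-tank trajectory
#'
#' Reflected Gaussian random walk inside the tank box.  The vertical
#' coordinate mean-reverts toward `preferred_depth_cm` with strength
#' `depth_bias` (1/s), emulating bottom-dwelling; the horizontal coordinates
#' drift toward the nearest wall with speed `wall_bias` (cm/s), emulating
#' thigmotaxis.  Zero biases give a symmetric walk whose stationary occupancy
#' is uniform over the box.
#'
#' @param subject_id Subject label.
#' @param duration_s Trial length (default 300 s, the 5-min assay).
#' @param dt_s Sampling interval.
#' @param depth_bias Mean-reversion rate toward the preferred depth, per
#'   second; 0 disables depth preference.
#' @param preferred_depth_cm Height above the floor the fish reverts to.
#' @param wall_bias Drift speed toward the nearest wall, cm/s; 0 disables.
#' @param step_sd_cms Diffusive step scale per axis, cm per sqrt(s); 0 yields
#'   a stationary trajectory.
#' @param cfg A [session_config()] carrying the tank dimensions.
#' @param start Optional `c(x, y, z)` start position; defaults to the tank
#'   centre at mid-depth.
#' @param seed Optional integer seed.
#' @return A list of two trajectory tibbles, `top` (`u` length, `v` width) and
#'   `front` (`u` length, `v` height), sharing timestamps.
#' @export
simulate_tank_trajectory <- function(subject_id = "f01",
                                     duration_s = 300,
                                     dt_s = 0.1,
                                     depth_bias = 0,
                                     preferred_depth_cm = 2,
                                     wall_bias = 0,
                                     step_sd_cms = 1.5,
                                     cfg = session_config(),
                                     start = NULL,
                                     seed = NULL) {
  if (duration_s <= 0 || dt_s <= 0) {
    parameter_error("duration_s and dt_s must be positive")
  }
  if (depth_bias < 0 || wall_bias < 0 || step_sd_cms < 0) {
    parameter_error("depth_bias, wall_bias and step_sd_cms must be non-negative")
  }
  L <- cfg$tank_length_cm
  W <- cfg$tank_width_cm
  H <- cfg$tank_height_cm
  start <- start %||% c(L / 2, W / 2, H / 2)
  maybe_with_seed(seed, {
    n <- floor(duration_s / dt_s) + 1
    times <- (seq_len(n) - 1) * dt_s
    x <- y <- z <- numeric(n)
    x[1] <- start[1]; y[1] <- start[2]; z[1] <- start[3]
    sdt <- step_sd_cms * sqrt(dt_s)
    ex <- rnorm(n - 1, sd = sdt)
    ey <- rnorm(n - 1, sd = sdt)
    ez <- rnorm(n - 1, sd = sdt)
    for (i in seq_len(n - 1)) {
      dx <- wall_bias * sign(x[i] - L / 2) * dt_s + ex[i]
      dy <- wall_bias * sign(y[i] - W / 2) * dt_s + ey[i]
      dz <- depth_bias * (preferred_depth_cm - z[i]) * dt_s + ez[i]
      x[i + 1] <- reflect_into(x[i] + dx, 0, L)
      y[i + 1] <- reflect_into(y[i] + dy, 0, W)
      z[i + 1] <- reflect_into(z[i] + dz, 0, H)
    }
    list(
      top = tibble::tibble(subject_id = subject_id, time_s = times,
                           u = x, v = y, view = "top"),
      front = tibble::tibble(subject_id = subject_id, time_s = times,
                             u = x, v = z, view = "front")
    )
  })
}

#' Simulate an avoidance-conditioning trajectory
#'
#' One-dimensional reflected walk along the conditioning tank's length (with a
#' free lateral coordinate), with zero drift through habituation and baseline
#' and, once a CS+ end is scheduled (the probe), a drift of
#' `avoidance_strength` cm/s pointing away from the current CS+ side —
#' tracking the mid-probe side swap.  Strength 0 is the null model: probe
#' preference matches baseline preference in expectation.
#'
#' @param avoidance_strength Drift away from CS+, cm/s, non-negative.
#' @param schedule A [conditioning_schedule()].
#' @param subject_id Subject label.
#' @param dt_s Sampling interval.
#' @param step_sd_cms Diffusive step scale, cm per sqrt(s).
#' @param include_habituation Simulate from session start instead of from the
#'   baseline phase (habituation is never scored, so the default skips it).
#' @param start_u Optional start position along the length; defaults to the
#'   midline.
#' @param seed Optional integer seed.
#' @return A top-view trajectory tibble (`subject_id`, `time_s`, `u`, `v`,
#'   `view`).
#' @export
simulate_conditioning_trajectory <- function(avoidance_strength = 0,
                                             schedule = conditioning_schedule(),
                                             subject_id = "f01",
                                             dt_s = 0.1,
                                             step_sd_cms = 2,
                                             include_habituation = FALSE,
                                             start_u = NULL,
                                             seed = NULL) {
  if (avoidance_strength < 0) {
    parameter_error("avoidance_strength must be non-negative")
  }
  stopifnot(inherits(schedule, "conditioning_schedule"))
  ph <- schedule$phases
  t0 <- if (include_habituation) 0 else ph$start_s[ph$phase == "baseline"]
  t_end <- ph$end_s[ph$phase == "probe"]
  L <- schedule$tank_length_cm
  W <- schedule$tank_width_cm
  probe <- cs_side_segments(schedule, "probe")
  maybe_with_seed(seed, {
    n <- floor((t_end - t0) / dt_s) + 1
    times <- t0 + (seq_len(n) - 1) * dt_s
    u <- v <- numeric(n)
    u[1] <- start_u %||% (L / 2)
    v[1] <- W / 2
    sdt <- step_sd_cms * sqrt(dt_s)
    eu <- rnorm(n - 1, sd = sdt)
    ev <- rnorm(n - 1, sd = sdt)
    in_probe <- findInterval(times, c(probe$start_s[1], probe$end_s[nrow(probe)]))
    for (i in seq_len(n - 1)) {
      drift <- 0
      if (avoidance_strength > 0 && in_probe[i] == 1) {
        side <- probe$side[times[i] < probe$end_s][1]
        drift <- if (side == "left") avoidance_strength else -avoidance_strength
      }
      u[i + 1] <- reflect_into(u[i] + drift * dt_s + eu[i], 0, L)
      v[i + 1] <- reflect_into(v[i] + ev[i], 0, W)
    }
    tibble::tibble(subject_id = subject_id, time_s = times, u = u, v = v,
                   view = "top")
  })
}
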