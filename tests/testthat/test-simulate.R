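test_that("degenerate chains produce their forced sequences", {
  expect_equal(unique(simulate_tokens(200, 1, 1, seed = 1)), "R")
  toks <- simulate_tokens(200, 1, 0, seed = 2)
  expect_true(all(toks[-1] != toks[-200])) # perfect alternation after the draw
  expect_error(turn_model_params(0.5, 0.5, turn_rate_per_min = 0),
               class = "lateralize_parameter_error")
  expect_error(turn_model_params(1.2, 0.5),
               class = "lateralize_parameter_error")
})

test_that("the empirical right-turn rate matches the stationary solution", {
  a <- 0.6
  b <- 0.7
  # closed form against an independent eigen-solution of the 2-state chain
  P <- matrix(c(1 - a, a, 1 - b, b), nrow = 2, byrow = TRUE)
  ev <- eigen(t(P))
  pi_eig <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_eig <- pi_eig / sum(pi_eig)
  expect_equal(stationary_R(a, b), pi_eig[2], tolerance = 1e-12)
  expect_equal(stationary_R(a, b), 2 / 3, tolerance = 1e-12)

  toks <- simulate_tokens(10000, a, b, seed = 19)
  se <- sqrt((2 / 3) * (1 / 3) / 10000)
  expect_lt(abs(mean(toks == "R") - 2 / 3), 3 * se)
})

test_that("expected tetragram frequencies agree with brute-force enumeration", {
  fair <- expected_tetragram_freqs(0.5, 0.5)
  expect_equal(fair$freq, rep(1 / 16, 16))

  absorbing <- expected_tetragram_freqs(1, 1)
  expect_equal(absorbing$freq[absorbing$word == "rrrr"], 1)
  expect_equal(sum(absorbing$freq), 1)

  for (ab in list(c(0.6, 0.7), c(0.3, 0.8), c(0.72, 0.72), c(0.65, 0.35))) {
    ours <- expected_tetragram_freqs(ab[1], ab[2])
    oracle <- enum_tetragram_freqs(ab[1], ab[2])
    expect_equal(ours$freq, unname(oracle[ours$word]), tolerance = 1e-12)
    expect_equal(sum(ours$freq), 1, tolerance = 1e-12)
  }

  expect_warning(deg <- expected_tetragram_freqs(0, 1), "stationary")
  expect_true(all(is.na(deg$freq)))
})

test_that("simulated sessions carry a decodable arm path and exact timing", {
  params <- turn_model_params(0.6, 0.4, turn_rate_per_min = 3)
  sim <- simulate_turn_sequence(params, seed = 7, subject_id = "fx")
  expect_true(all(sim$turns$time_s <= 3600))
  expect_true(!is.unsorted(sim$turns$time_s))
  decoded <- events_to_turns(sim$events)
  expect_equal(decoded$token, sim$turns$token)
  expect_equal(decoded$time_s, sim$turns$time_s)
  # identical seed, identical output; the caller's RNG stream is untouched
  again <- simulate_turn_sequence(params, seed = 7, subject_id = "fx")
  expect_identical(again$turns, sim$turns)
})

test_that("transition probabilities are recovered from 2000-turn streams", {
  ok <- vapply(1:25, function(s) {
    est <- estimate_turn_model(simulate_tokens(2000, 0.65, 0.35, seed = s))
    abs(est$a_hat - 0.65) <= 0.05 && abs(est$b_hat - 0.35) <= 0.05
  }, logical(1))
  expect_true(all(ok))
})

test_that("cohort simulation is deterministic with faithful ground truth", {
  spec <- cohort_spec(n_left = 1, n_right = 1, n_non = 1, random_seed = 5)
  sim <- simulate_cohort(spec)
  expect_equal(nrow(sim$truth), 3)
  expect_equal(dplyr::n_distinct(sim$events$subject_id), 3)
  expect_equal(sort(unique(sim$truth$class)),
               c("left_biased", "non_biased", "right_biased"))
  sim2 <- simulate_cohort(spec)
  expect_identical(sim$events, sim2$events)
  expect_identical(sim$truth, sim2$truth)
  expect_error(cohort_spec(0, 0, 0), class = "lateralize_parameter_error")
})

test_that("tank walks respect their degenerate and biased limits", {
  still <- simulate_tank_trajectory(step_sd_cms = 0, duration_s = 10, seed = 1)
  expect_equal(length(unique(still$top$u)), 1)
  expect_equal(tank_endpoints(still$front, still$top)$distance_cm, 0)

  # unbiased long walk: thirds occupancy near 1/3 each across replicates
  shares <- t(vapply(1:20, function(i) {
    sim <- simulate_tank_trajectory(duration_s = 120, step_sd_cms = 3,
                                    seed = 200 + i)
    res <- tank_endpoints(sim$front, sim$top)
    c(res$time_bottom_s, res$time_middle_s, res$time_top_s) / res$covered_s
  }, numeric(3)))
  m <- colMeans(shares)
  se <- apply(shares, 2, stats::sd) / sqrt(nrow(shares))
  expect_true(all(abs(m - 1 / 3) <= 3 * se + 0.02))
})

test_that("conditioning walks are null at zero strength and monotone in it", {
  sched <- conditioning_schedule()
  mean_probe <- function(strength, seeds) {
    mean(vapply(seeds, function(s) {
      traj <- simulate_conditioning_trajectory(strength, sched, seed = s)
      preference_fraction(traj, sched, "probe")$cs_plus_fraction
    }, numeric(1)))
  }
  deltas <- vapply(1:30, function(s) {
    traj <- simulate_conditioning_trajectory(0, sched, seed = 300 + s)
    pr <- conditioning_preference(traj, sched)
    pr$delta_pref
  }, numeric(1))
  # paired baseline/probe difference centred on zero under the null
  expect_lt(abs(mean(deltas)), 3 * stats::sd(deltas) / sqrt(length(deltas)))

  probes <- vapply(c(0, 1, 4), mean_probe, numeric(1), seeds = 400 + 1:15)
  expect_true(all(diff(probes) < 0))
  expect_lt(probes[3], 0.25) # strong avoidance pins the fish off CS+
})

test_that("all generators reproduce byte-identical output under one seed", {
  t1 <- simulate_tank_trajectory(seed = 8, duration_s = 5)
  t2 <- simulate_tank_trajectory(seed = 8, duration_s = 5)
  expect_identical(t1, t2)
  c1 <- simulate_conditioning_trajectory(1, seed = 8)
  c2 <- simulate_conditioning_trajectory(1, seed = 8)
  expect_identical(c1, c2)
})
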