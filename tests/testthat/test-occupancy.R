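probe_window <- function(sched) {
  ph <- sched$phases
  c(ph$start_s[ph$phase == "probe"], ph$end_s[ph$phase == "probe"])
}

test_that("phase windows are contiguous and non-overlapping", {
  ph <- conditioning_schedule()$phases
  expect_equal(ph$start_s[-1], ph$end_s[-4])
  expect_equal(ph$start_s[1], 0)
  expect_equal(ph$end_s[4] - ph$start_s[4], 60)
  expect_equal(ph$start_s[4], 1800 + 600 + 9 * (1.5 + 8.5))
})

test_that("a fish parked on the CS- side scores zero probe preference", {
  sched <- conditioning_schedule(probe_cs_first_side = "left")
  win <- probe_window(sched)
  # right half for the first 30 s, left half after the swap: always opposite CS+
  ts <- seq(win[1], win[2] - 0.1, by = 0.1)
  traj <- tibble::tibble(
    subject_id = "f1", time_s = ts,
    u = ifelse(ts < win[1] + 30, 20, 5), v = 7
  )
  pref <- preference_fraction(traj, sched, "probe")
  expect_equal(pref$cs_plus_fraction, 0)
  expect_equal(pref$covered_s, 60)
})

test_that("a stationary fish scores exactly half across the probe swap", {
  sched <- conditioning_schedule()
  win <- probe_window(sched)
  traj <- tibble::tibble(
    subject_id = "f1",
    time_s = seq(win[1], win[2] - 0.5, by = 0.5),
    u = 5, v = 7
  )
  expect_equal(preference_fraction(traj, sched, "probe")$cs_plus_fraction, 0.5)
  # same at baseline: the 600-s window spans exactly one side alternation
  base <- tibble::tibble(
    subject_id = "f1", time_s = seq(1800, 2399.5, by = 0.5), u = 5, v = 7
  )
  expect_equal(preference_fraction(base, sched, "baseline")$cs_plus_fraction, 0.5)
})

test_that("CS+ and CS- fractions are complementary for covered phases", {
  sched <- conditioning_schedule(probe_cs_first_side = "left")
  flipped <- conditioning_schedule(probe_cs_first_side = "right")
  traj <- simulate_conditioning_trajectory(0, sched, seed = 2)
  a <- preference_fraction(traj, sched, "probe")$cs_plus_fraction
  b <- preference_fraction(traj, flipped, "probe")$cs_plus_fraction
  expect_equal(a + b, 1)
})

test_that("sampling gaps inside a phase warn and score over covered time", {
  sched <- conditioning_schedule()
  win <- probe_window(sched)
  traj <- tibble::tibble(
    subject_id = "f1",
    time_s = c(seq(win[1], win[1] + 10, by = 0.5),
               seq(win[1] + 40, win[2] - 0.5, by = 0.5)),
    u = 5, v = 7
  )
  expect_warning(pref <- preference_fraction(traj, sched, "probe"), "gap")
  # 21 samples x 0.5 s before the gap (last one zeroed), 40 x 0.5 s after
  expect_equal(pref$covered_s, 30)
  # on the CS+ side for the 10 covered pre-gap seconds, opposite it for the
  # 20 covered post-swap seconds
  expect_equal(pref$cs_plus_fraction, 1 / 3)
})

test_that("preference honours the baseline side-alternation cadence", {
  sched <- conditioning_schedule(cs_start_side = "left")
  # occupy [1800, 2100) only: CS+ shows on the left there (block index even)
  traj <- tibble::tibble(
    subject_id = "f1", time_s = seq(1800, 2099.5, by = 0.5), u = 5, v = 7
  )
  expect_warning(pref <- preference_fraction(traj, sched, "baseline"), "gap")
  expect_equal(pref$cs_plus_fraction, 1)
})

test_that("novel-tank endpoints are exact for engineered trajectories", {
  cfg <- session_config()
  # stationary fish at mid-depth, centre of the footprint
  ts <- seq(0, 300, by = 0.5)
  front <- tibble::tibble(subject_id = "f1", time_s = ts, u = 15, v = 7.5)
  top <- tibble::tibble(subject_id = "f1", time_s = ts, u = 15, v = 6)
  res <- tank_endpoints(front, top, cfg)
  expect_equal(res$time_middle_s, 300)
  expect_equal(res$time_bottom_s + res$time_top_s, 0)
  expect_equal(res$distance_cm, 0)
  expect_equal(res$immobility_s, 300)
  expect_equal(res$thigmotaxis_s, 0)

  # fish tracing the perimeter inside the margin at constant speed
  per <- 2 * (cfg$tank_length_cm + cfg$tank_width_cm)
  s <- (ts * 2) %% per # 2 cm/s along the wall
  u <- pmin(pmax(ifelse(s < 30, s,
                 ifelse(s < 42, 30, ifelse(s < 72, 72 - s, 0))), 0), 30)
  v <- pmin(pmax(ifelse(s < 30, 0,
                 ifelse(s < 42, s - 30, ifelse(s < 72, 12, 84 - s))), 0), 12)
  top2 <- tibble::tibble(subject_id = "f1", time_s = ts, u = u, v = v)
  front2 <- tibble::tibble(subject_id = "f1", time_s = ts, u = u, v = 2)
  res2 <- tank_endpoints(front2, top2, cfg)
  expect_equal(res2$thigmotaxis_s, 300)
  expect_equal(res2$time_bottom_s, 300)
  expect_equal(res2$immobility_s, 0)
  expect_equal(res2$distance_cm, 600, tolerance = 0.05)
})

test_that("thirds occupancy partitions the covered time", {
  cfg <- session_config()
  withr::with_seed(11, {
    for (i in 1:5) {
      sim <- simulate_tank_trajectory("f1", duration_s = 30, seed = i)
      res <- tank_endpoints(sim$front, sim$top, cfg)
      expect_equal(
        res$time_bottom_s + res$time_middle_s + res$time_top_s,
        res$covered_s,
        tolerance = 1e-9
      )
    }
  })
})

test_that("distance is translation-invariant and views must share a time base", {
  cfg <- session_config()
  sim <- simulate_tank_trajectory("f1", duration_s = 30, seed = 4,
                                  step_sd_cms = 0.5,
                                  start = c(10, 6, 7.5))
  res <- tank_endpoints(sim$front, sim$top, cfg)
  shifted <- dplyr::mutate(sim$top, u = u + 3) # rigid shift along the length
  res_shift <- tank_endpoints(sim$front, shifted, cfg)
  expect_equal(res_shift$distance_cm, res$distance_cm)

  late <- dplyr::mutate(sim$top, time_s = time_s + 0.05)
  expect_error(tank_endpoints(sim$front, late, cfg),
               "time bases", class = "lateralize_data_error")
})

test_that("a bottom-biased walk spends more time low than high", {
  hits <- vapply(1:40, function(i) {
    sim <- simulate_tank_trajectory("f1", duration_s = 60, depth_bias = 1,
                                    preferred_depth_cm = 2, seed = 100 + i)
    res <- tank_endpoints(sim$front, sim$top)
    res$time_bottom_s > res$time_top_s
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
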