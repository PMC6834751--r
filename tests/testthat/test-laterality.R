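test_that("bias percentage follows the turns formula and is missing at zero turns", {
  expect_equal(bias_percentage(c(rep("R", 7), rep("L", 3)), "R"), 70)
  expect_equal(bias_percentage(c(rep("R", 7), rep("L", 3)), "L"), 30)
  expect_equal(bias_percentage(rep("L", 12), "L"), 100)
  expect_true(is.na(bias_percentage(character(0), "R")))
  expect_error(bias_percentage(c("L", "X")), class = "lateralize_data_error")
})

test_that("a seeded Bernoulli stream lands in the binomial 99% interval", {
  toks <- simulate_tokens(500, 0.65, 0.65, seed = 17)
  half_width <- 100 * stats::qnorm(0.995) * sqrt(0.65 * 0.35 / 500)
  expect_lt(abs(bias_percentage(toks, "R") - 65), half_width)
})

test_that("left and right percentages are complementary for any sequence", {
  withr::with_seed(7, {
    for (i in 1:20) {
      toks <- sample(c("L", "R"), sample(1:200, 1), replace = TRUE)
      expect_equal(bias_percentage(toks, "L") + bias_percentage(toks, "R"), 100)
    }
  })
})

test_that("across-bin consistency reproduces closed-form mean and CV", {
  cfg <- session_config()
  # identical 70% R in all six bins: zero variance
  toks <- rep(c(rep("R", 7), rep("L", 3)), 6)
  times <- as.vector(vapply(0:5, function(b) b * 600 + 1:10, numeric(10)))
  cons <- per_bin_consistency(make_turns(toks, times = times), cfg)
  expect_equal(cons$n_bins_used, 6)
  expect_equal(cons$mean_R_pct, 70)
  expect_equal(cons$cv_R_pct, 0)

  # two usable bins at 60% and 80% R: sample-SD convention
  toks2 <- c(rep("R", 6), rep("L", 4), rep("R", 8), rep("L", 2))
  times2 <- c(1:10, 601:610)
  cons2 <- per_bin_consistency(make_turns(toks2, times = times2), cfg)
  expect_equal(cons2$n_bins_used, 2)
  expect_equal(cons2$n_bins_empty, 4)
  expect_equal(cons2$mean_R_pct, 70)
  expect_equal(cons2$cv_R_pct, 100 * sqrt(200) / 70) # sd(c(60, 80)) = sqrt(200)
  expect_equal(cons2$cv_L_pct, 100 * sqrt(200) / 30)

  # a single usable bin leaves consistency undefined
  cons1 <- per_bin_consistency(make_turns(c("L", "R"), times = c(1, 2)), cfg)
  expect_true(is.na(cons1$cv_R_pct) && is.na(cons1$mean_R_pct))
})

test_that("a stationary biased simulant keeps its CV under the stability bound", {
  cfg <- session_config()
  toks <- simulate_tokens(600, 0.72, 0.72, seed = 23)
  times <- seq(0.5, 3599.5, length.out = 600) # 100 turns per bin
  cons <- per_bin_consistency(make_turns(toks, times = times), cfg)
  expect_equal(cons$n_bins_used, 6)
  expect_lt(cons$cv_R_pct, 20)
})

test_that("classification is strict at the threshold and three-way", {
  expect_equal(classify_laterality(40, 60), "non_biased")
  expect_equal(classify_laterality(39.9, 60.1), "right_biased")
  expect_equal(classify_laterality(60.1, 39.9), "left_biased")
  expect_true(is.na(classify_laterality(NA_real_, NA_real_)))
  expect_error(classify_laterality(50, 50, threshold_pct = 50),
               class = "lateralize_parameter_error")
})

test_that("flipping all tokens swaps the lateral labels and fixes non_biased", {
  cfg <- session_config()
  withr::with_seed(31, {
    for (p in c(0.3, 0.5, 0.8)) {
      toks <- sample(c("L", "R"), 120, replace = TRUE, prob = c(1 - p, p))
      turns <- make_turns(toks, times = sort(runif(120, 0, 3600)))
      flipped <- dplyr::mutate(turns, token = ifelse(token == "R", "L", "R"))
      lab <- subject_laterality(turns, cfg)$label
      lab_f <- subject_laterality(flipped, cfg)$label
      swap <- c(left_biased = "right_biased", right_biased = "left_biased",
                non_biased = "non_biased")
      expect_equal(lab_f, unname(swap[lab]))
      expect_true(lab %in% c("left_biased", "right_biased", "non_biased"))
    }
  })
})

test_that("subjects below the engagement threshold are flagged, zero-turn subjects reported", {
  cfg <- session_config(min_turns_for_inclusion = 20)
  turns <- dplyr::bind_rows(
    make_turns(rep(c("L", "R"), 15), subject = "busy",
               times = sort(runif(30, 0, 3600))),
    make_turns(c("L", "R", "L"), subject = "idle", times = c(1, 2, 3))
  )
  res <- subject_laterality(turns, cfg, subjects = c("busy", "idle", "ghost"))
  expect_equal(nrow(res), 3)
  expect_true(res$included[res$subject_id == "busy"])
  expect_false(res$included[res$subject_id == "idle"])
  ghost <- res[res$subject_id == "ghost", ]
  expect_false(ghost$included)
  expect_true(is.na(ghost$label) && is.na(ghost$bias_R_pct))
})

test_that("cohort class percentages are exact count ratios", {
  res <- tibble::tibble(label = "right_biased", included = TRUE)
  cs <- cohort_class_summary(res)
  expect_equal(cs$pct[cs$label == "right_biased"], 100)
  expect_equal(sum(cs$n), 1)

  withr::with_seed(41, {
    draws <- sample(c("left_biased", "right_biased", "non_biased"), 60,
                    replace = TRUE)
    cs2 <- cohort_class_summary(tibble::tibble(label = draws, included = TRUE))
    for (lab in unique(draws)) {
      expect_equal(cs2$pct[cs2$label == lab], 100 * sum(draws == lab) / 60)
    }
  })

  expect_error(
    cohort_class_summary(tibble::tibble(label = "non_biased", included = FALSE)),
    class = "lateralize_data_error"
  )
})
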