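test_that("absorbing dynamics force constant trajectories (only P5 or P8)", {
  cfg <- simulation_config(200, default_item_params(pi = 0.4, rho = 1,
                                                    omega = 0),
                           seed = 11)
  pm <- derive_pattern_features(simulate_panel(cfg))
  info <- attr(pm, "pattern_info")
  item_cols <- info$column[info$n_members == 1L]
  active <- info$pattern[info$column %in% item_cols][
    colSums(pm[, item_cols, drop = FALSE]) > 0]
  expect_true(all(active %in% c("P5", "P8")))
  # every item is either persistently present or consistently absent
  p5 <- pm[, info$column[info$pattern == "P5" & info$n_members == 1L]]
  p8 <- pm[, info$column[info$pattern == "P8" & info$n_members == 1L]]
  expect_true(all(p5 + p8 == 1))
})

test_that("a zero-prevalence zero-onset configuration yields an all-absent panel", {
  cfg <- simulation_config(50, default_item_params(pi = 0, omega = 0),
                           seed = 2)
  panel <- simulate_panel(cfg)
  expect_true(all(panel$responses == 0L))
  ms <- build_cross_sectional_measures(panel)
  expect_true(all(ms[, "overall_summary", ] == 0))
})

test_that("empirical wave prevalences match the two-state Markov marginals", {
  pi <- 0.3; rho <- 0.7; omega <- 0.1; n <- 10000L
  cfg <- simulation_config(n, default_item_params(pi = pi, rho = rho,
                                                  omega = omega), seed = 5)
  panel <- simulate_panel(cfg)
  # closed-form chain marginals as the oracle
  p2 <- pi * rho + (1 - pi) * omega
  p3 <- p2 * rho + (1 - p2) * omega
  for (w in 1:3) {
    target <- c(pi, p2, p3)[w]
    emp <- mean(panel$responses[, , w])
    se <- sqrt(target * (1 - target) / (n * 37))
    expect_lt(abs(emp - target), 3 * se)
  }
})

test_that("invalid item probabilities are rejected naming the item", {
  ip <- default_item_params()
  ip$rho[ip$item == "migraine"] <- 1.4
  expect_error(simulation_config(10, ip), "migraine")
  expect_error(simulation_config(0), "positive")
})

test_that("panel and outcome are bit-identical under a fixed seed", {
  cfg <- simulation_config(80, missing_rate = 0.05, seed = 99)
  expect_identical(simulate_panel(cfg)$responses,
                   simulate_panel(cfg)$responses)
  ch1 <- cohort_preset("pattern_driven", n_subjects = 60, seed = 3)
  ch2 <- cohort_preset("pattern_driven", n_subjects = 60, seed = 3)
  expect_identical(ch1$panel$responses, ch2$panel$responses)
  expect_identical(ch1$outcome, ch2$outcome)
  expect_identical(ch1$covariates, ch2$covariates)
})

test_that("outcomes follow the specified sparse truth", {
  cfg <- simulation_config(4000, seed = 21)
  panel <- simulate_panel(cfg)

  # noiseless empty support: every score equals the intercept exactly
  y0 <- simulate_outcome(panel, truth = true_model_spec(noise_sd = 0),
                         seed = 1)
  expect_true(all(y0 == 50))

  # single binary effect: sample-mean contrast recovers beta = -10
  truth <- true_model_spec(
    support = data.frame(measure = "feeling_weak", pattern = "P8",
                         beta = -10),
    noise_sd = 10)
  y <- simulate_outcome(panel, truth = truth, seed = 7)
  f <- derive_pattern_features(panel)[, "feeling_weak__P8"]
  contrast <- mean(y[f == 1]) - mean(y[f == 0])
  se <- 10 * sqrt(1 / sum(f == 1) + 1 / sum(f == 0))
  expect_lt(abs(contrast - (-10)), 3 * se)

  # pure-noise outcome has the nominal SD
  y2 <- simulate_outcome(simulate_panel(simulation_config(5000, seed = 8)),
                         truth = true_model_spec(noise_sd = 10), seed = 9)
  expect_lt(abs(sd(y2) - 10), 3 * 10 / sqrt(2 * (5000 - 1)))

  # invalid support is rejected
  expect_error(true_model_spec(
    support = data.frame(measure = "memory_summary", pattern = "P5",
                         beta = 1)), "invalid")
})

test_that("default dynamics keep consistent absence dominant and persistence rare", {
  panel <- simulate_panel(simulation_config(2000, seed = 13))
  pm <- derive_pattern_features(panel)
  info <- attr(pm, "pattern_info")
  item_prev <- sapply(paste0("P", c(1:10)), function(p)
    mean(pm[, info$column[info$pattern == p & info$n_members == 1L]]))
  expect_equal(which.max(item_prev), c(P8 = 8L))
  # theoretical item-level persistent-presence prevalence is pi * rho^2
  # <= 0.22 * 0.55^2 ~ 0.067; allow 3 binomial MC SEs at n = 2000
  p5 <- colMeans(pm[, info$column[info$pattern == "P5" &
                                    info$n_members == 1L]])
  expect_true(all(p5 <= 0.067 + 3 * sqrt(0.067 * 0.933 / 2000)))
  p8 <- colMeans(pm[, info$column[info$pattern == "P8" &
                                    info$n_members == 1L]])
  expect_true(all(p8 >= 0.417 & p8 <= 0.981))
})

test_that("a cohort round-trips through its delimited representation", {
  ch <- cohort_preset("null", n_subjects = 12, seed = 4)
  d <- withr::local_tempdir()
  paths <- write_cohort(ch, d)
  back <- as_symptom_panel(utils::read.delim(paths[1L]))
  expect_identical(back$responses, ch$panel$responses)
  cov_back <- utils::read.delim(paths[2L])
  expect_equal(cov_back$age_t1, ch$covariates$age_t1)
  out_back <- utils::read.delim(paths[3L])
  expect_equal(out_back$hrqol, unname(ch$outcome))
})
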