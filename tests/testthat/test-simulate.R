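# Synthetic-cohort generation, exclusions, and generative/fitting
# consistency.

small_config <- function(...) {
  cohort_config(n_participants = 3, seed = 123, ...)
}

test_that("calibration simulation reproduces the stimulus-response
           structure", {
  cfg <- small_config(noise_sd = 0)
  truth <- sample_truth(cfg)
  cal <- simulate_calibration(truth, cfg, seed = 5)
  # zero noise: cell means strictly increasing in intensity (positive slopes)
  for (g in split(cal$calibration, list(cal$calibration$participant,
                                        cal$calibration$modality))) {
    expect_true(all(diff(g$calib_mean[order(g$intensity_level)]) > 0))
  }
  cfg6 <- small_config()
  cal6 <- simulate_calibration(sample_truth(cfg6), cfg6, seed = 5)
  for (m in c("pain", "vision")) {
    sl <- coef(lm(rating ~ intensity_level,
                  data = cal6$trials[cal6$trials$modality == m, ]))[2]
    expect_gt(sl, 0)
  }
})

test_that("calibration cell means have the expected standard error", {
  cfg <- cohort_config(n_participants = 30, seed = 7, noise_sd = 6,
                       calib_intercept_sd = 0, calib_slope_sd = 0)
  truth <- sample_truth(cfg)
  cal <- simulate_calibration(truth, cfg, seed = 8)
  # with 5 reps/cell the cell-mean SE is 6/sqrt(5); clipping is negligible
  # at interior cells
  interior <- cal$calibration[cal$calibration$intensity_level %in% 2:4, ]
  expected <- 10 + 12 * interior$intensity_level
  expected[interior$modality == "vision"] <-
    8 + 16 * interior$intensity_level[interior$modality == "vision"]
  se <- sd(interior$calib_mean - expected)
  expect_equal(se, 6 / sqrt(5), tolerance = 0.2)
})

test_that("expectation-task simulation is exact at zero noise and
           reproducible", {
  cfg <- small_config(noise_sd = 0, k_sdlog = 1e-9, b_sd = 1e-9,
                      k_center = c(pain = 1, vision = 1),
                      b_center = c(pain = 0, vision = 0))
  truth <- sample_truth(cfg)
  tr <- simulate_expectation_task(truth, cfg, seed = 31)
  expect_equal(tr$expectation_rating, rowMeans(cue_values(tr)),
               tolerance = 1e-6)
  tr2 <- simulate_expectation_task(truth, cfg, seed = 31)
  expect_identical(tr, tr2)
  tr3 <- simulate_expectation_task(truth, cfg, seed = 32)
  expect_false(identical(tr$expectation_rating, tr3$expectation_rating))
})

test_that("the configured response-time outlier fraction is flagged by the
           exclusion filter", {
  cfg <- cohort_config(n_participants = 10, seed = 9,
                       rt_outlier_frac = 0.07)
  truth <- sample_truth(cfg)
  tr <- simulate_expectation_task(truth, cfg, seed = 33)
  ex <- exclude_trials(tr)
  frac <- 1 - nrow(ex$trials) / nrow(tr)
  expect_equal(frac, 0.07, tolerance = 0.2)
  expect_identical(nrow(tr) - nrow(ex$trials),
                   sum(ex$log$n_too_fast + ex$log$n_too_slow))
})

test_that("the exclusion rule keeps the closed 0.2-4.5 s window", {
  tr <- data.frame(participant = 1,
                   response_time_s = c(0.1, 0.3, 4.6, 2.0, 0.2, 4.5))
  ex <- exclude_trials(tr)
  expect_equal(ex$trials$response_time_s, c(0.3, 2.0, 0.2, 4.5))
  expect_identical(ex$log$n_too_fast, 1L)
  expect_identical(ex$log$n_too_slow, 1L)
  # all in range: identity
  ok <- data.frame(participant = 1, response_time_s = c(1, 2, 3))
  expect_identical(exclude_trials(ok)$trials, ok)
  expect_error(exclude_trials(data.frame(x = 1)), "response_time_s")
})

test_that("perception-task simulation honours the generating model", {
  # M2 with w = 1 and zero noise reproduces the cue-based expectations
  cfg <- small_config(noise_sd = 0, w_range = c(1, 1),
                      perception_model = "M2")
  truth <- sample_truth(cfg)
  cal <- simulate_calibration(truth, cfg, seed = 41)
  tr <- simulate_perception_task(truth, cfg, cal$calibration, seed = 42)
  expect_equal(tr$perception_rating, tr$expectation, tolerance = 1e-9)
  # learning model trajectories come from run_learning's simulate mode
  cfg3 <- small_config(noise_sd = 0, perception_model = "M3")
  truth3 <- sample_truth(cfg3)
  tr3 <- simulate_perception_task(truth3, cfg3, cal$calibration, seed = 43)
  one <- tr3[tr3$participant == 1, ]
  pars <- perception_params("M3", s_p = truth3$s_p[1], s_v = truth3$s_v[1],
                            w0 = truth3$w[1], alpha = truth3$alpha[1])
  redo <- run_learning(one, pars, mode = "simulate", noise_sd = 0)
  expect_equal(one$perception_rating, redo$ratings)
  expect_equal(one$w_true, redo$w)
  bad <- truth3
  bad$model <- "M9"
  expect_error(simulate_perception_task(bad, cfg3, cal$calibration, 44),
               "unknown generating model")
})

test_that("simulated cohorts are byte-identical under the same seed", {
  cfg <- small_config()
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$expectation_trials, c2$expectation_trials)
  expect_identical(c1$perception_trials, c2$perception_trials)
  expect_identical(c1$calibration, c2$calibration)
})

test_that("a noiseless cohort is recovered essentially exactly end to end", {
  cfg <- cohort_config(n_participants = 6, seed = 77, noise_sd = 0,
                       rt_outlier_frac = 0,
                       perception_model = c("M1", "M2", "M3", "M4", "M5"))
  rep <- recovery_study(cfg, use_true_expectation = TRUE)
  for (m in c("pain", "vision")) {
    expect_gt(rep$expectation_recovery[[m]]$k$spearman, 0.99)
    expect_lt(rep$expectation_recovery[[m]]$b$rmse, 1e-2)
  }
  # every generating model identified by AIC on its own noiseless data
  expect_identical(sum(diag(rep$confusion)), 6L)
  expect_output(print(rep), "Model identification")
})
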