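# The five nested observer models: prediction, learning dynamics, fitting.

test_that("free-parameter sets are exactly those of the five models", {
  expect_identical(perception_param_names("M1"), c("s_p", "s_v"))
  expect_identical(perception_param_names("M2"), c("s_p", "s_v", "w"))
  expect_identical(perception_param_names("M3"),
                   c("s_p", "s_v", "w0", "alpha"))
  expect_identical(perception_param_names("M4"),
                   c("s_p", "s_v", "w_p", "w_v"))
  expect_identical(perception_param_names("M5"),
                   c("s_p", "s_v", "w0_p", "w0_v", "alpha_p", "alpha_v"))
  expect_identical(vapply(paste0("M", 1:5),
                          function(m) length(perception_param_names(m)), 0L),
                   c(M1 = 2L, M2 = 3L, M3 = 4L, M4 = 4L, M5 = 6L))
  expect_error(perception_params("M2", s_p = 1, s_v = 1), "exactly")
  expect_error(perception_params("M2", s_p = 6, s_v = 1, w = 0.5), "bounds")
  expect_error(perception_params("M3", s_p = 1, s_v = 1, w0 = 0.5,
                                 alpha = 1.2), "bounds")
})

test_that("calibration tables aggregate cell means and warn on
           non-monotone intensity profiles", {
  trials <- expand.grid(participant = 1:2, modality = c("pain", "vision"),
                        intensity_level = 1:5, rep = 1:5,
                        stringsAsFactors = FALSE)
  trials$rating <- 10 + 12 * trials$intensity_level + (trials$rep - 3)
  tab <- calibration_table(trials)
  expect_identical(nrow(tab), 20L)
  expect_equal(tab$calib_mean, 10 + 12 * tab$intensity_level)
  bad <- trials
  bad$rating[bad$participant == 1 & bad$modality == "pain" &
               bad$intensity_level == 5] <- 0
  expect_warning(calibration_table(bad), "nondecreasing")
  expect_error(attach_calibration(
    data.frame(participant = 9, modality = "pain", intensity_level = 1),
    tab), "missing calibration cell")
})

test_that("static model predictions match hand-evaluated cases", {
  tr <- data.frame(participant = 1, modality = c("pain", "vision"),
                   intensity_level = c(2, 2), calib = c(55, 40),
                   expectation = c(40, 40))
  p1 <- predict_perception(tr, perception_params("M1", s_p = 1, s_v = 2))
  expect_equal(p1, c(55, 80))
  # boundary weights: w = 0 reduces to M1, w = 1 to the expectation
  p0 <- predict_perception(tr, perception_params("M2", s_p = 1, s_v = 2,
                                                 w = 0))
  expect_equal(p0, p1)
  pw <- predict_perception(tr, perception_params("M2", s_p = 1, s_v = 2,
                                                 w = 1))
  expect_equal(pw, c(40, 40))
  # hand case: intensity*s = 60, expectation = 40, w = 0.5 -> 50
  tr2 <- data.frame(participant = 1, modality = "pain", intensity_level = 2,
                    calib = 60, expectation = 40)
  expect_equal(predict_perception(tr2, perception_params("M2", s_p = 1,
                                                         s_v = 1, w = 0.5)),
               50)
  # modality-specific weights
  p4 <- predict_perception(tr, perception_params("M4", s_p = 1, s_v = 2,
                                                 w_p = 1, w_v = 0))
  expect_equal(p4, c(40, 80))
})

test_that("prediction-error learning follows the clamped update rule", {
  # single trial hand case: PE = (80 - 30)/100, w1 = 0.5 - 0.5*0.5 = 0.25
  tr <- data.frame(modality = "pain", calib = 50, expectation = 30,
                   perception_rating = 80)
  rl <- run_learning(tr, perception_params("M3", s_p = 1, s_v = 1,
                                           w0 = 0.5, alpha = 0.5))
  expect_equal(rl$w, 0.5)          # weight in force on the trial
  expect_equal(rl$predictions, 0.5 * 50 + 0.5 * 30)
  # two trials expose the updated weight
  tr2 <- rbind(tr, tr)
  rl2 <- run_learning(tr2, perception_params("M3", s_p = 1, s_v = 1,
                                             w0 = 0.5, alpha = 0.5))
  expect_equal(rl2$w, c(0.5, 0.25))
})

test_that("alpha = 0 reduces the learning models to their static parents", {
  px <- small_perception_trials(seed = 41)
  tr <- px$trials
  set.seed(1)
  tr$perception_rating <- pmin(pmax(50 + rnorm(nrow(tr), 0, 20), 0), 100)
  m3 <- run_learning(tr, perception_params("M3", s_p = 1.1, s_v = 0.9,
                                           w0 = 0.4, alpha = 0))
  m2 <- predict_perception(tr, perception_params("M2", s_p = 1.1, s_v = 0.9,
                                                 w = 0.4))
  expect_equal(m3$predictions, m2)
  expect_true(all(m3$w == 0.4))
  m5 <- run_learning(tr, perception_params("M5", s_p = 1.1, s_v = 0.9,
                                           w0_p = 0.3, w0_v = 0.7,
                                           alpha_p = 0, alpha_v = 0))
  m4 <- predict_perception(tr, perception_params("M4", s_p = 1.1, s_v = 0.9,
                                                 w_p = 0.3, w_v = 0.7))
  expect_equal(m5$predictions, m4)
})

test_that("ratings persistently above expectations drive w down to the
           clamp under positive alpha", {
  n <- 30
  tr <- data.frame(modality = "pain", calib = rep(80, n),
                   expectation = rep(20, n),
                   perception_rating = rep(90, n))
  rl <- run_learning(tr, perception_params("M3", s_p = 1, s_v = 1,
                                           w0 = 0.9, alpha = 0.6))
  expect_true(all(diff(rl$w) <= 0))
  expect_true(all(rl$w >= 0 & rl$w <= 1))
  expect_equal(rl$w[n], 0)  # clamped at the floor
  # negative alpha saturates at the ceiling instead
  rl2 <- run_learning(tr, perception_params("M3", s_p = 1, s_v = 1,
                                            w0 = 0.1, alpha = -0.6))
  expect_true(all(diff(rl2$w) >= 0))
  expect_equal(rl2$w[n], 1)
})

test_that("M5 keeps independent weight streams per modality", {
  tr <- data.frame(modality = c("pain", "vision", "pain", "vision"),
                   calib = 50, expectation = 50,
                   perception_rating = c(100, 50, 100, 50))
  rl <- run_learning(tr, perception_params("M5", s_p = 1, s_v = 1,
                                           w0_p = 0.5, w0_v = 0.5,
                                           alpha_p = 0.4, alpha_v = 0.4))
  # pain stream updates on pain PEs only; vision PEs are zero
  expect_equal(rl$w, c(0.5, 0.5, 0.3, 0.5))
})

test_that("noiseless self-consistency: each model refits its own data", {
  px <- small_perception_trials(seed = 43)
  tr <- px$trials
  truths <- list(
    M1 = perception_params("M1", s_p = 1.2, s_v = 0.7),
    M2 = perception_params("M2", s_p = 1, s_v = 1, w = 0.6),
    M3 = perception_params("M3", s_p = 0.9, s_v = 1.1, w0 = 0.7,
                           alpha = 0.2),
    M4 = perception_params("M4", s_p = 1, s_v = 1, w_p = 0.3, w_v = 0.7),
    M5 = perception_params("M5", s_p = 1, s_v = 1, w0_p = 0.6, w0_v = 0.4,
                           alpha_p = 0.15, alpha_v = -0.1))
  for (m in names(truths)) {
    tr$perception_rating <- if (m %in% c("M3", "M5"))
      run_learning(tr, truths[[m]], mode = "simulate", noise_sd = 0)$ratings
    else predict_perception(tr, truths[[m]])
    f <- fit_perception(tr, m)
    expect_lt(f$rss, 1e-4)
    expect_equal(unname(f$params), unname(truths[[m]]$par), tolerance = 1e-2)
    expect_identical(length(f$params),
                     length(perception_param_names(m)))
  }
})

test_that("data from the baseline model yield a near-zero fitted cue
           weight in M2", {
  px <- small_perception_trials(seed = 44)
  tr <- px$trials
  set.seed(9)
  tr$perception_rating <- pmin(pmax(
    predict_perception(tr, perception_params("M1", s_p = 1, s_v = 1)) +
      rnorm(nrow(tr), 0, 6), 0), 100)
  f2 <- fit_perception(tr, "M2")
  expect_lt(f2$params[["w"]], 0.12)
  # nesting inequality: the richer model can never fit worse
  f1 <- fit_perception(tr, "M1")
  expect_lte(f2$rss, f1$rss + 1e-6)
})

test_that("fitting validates trial counts and required columns", {
  px <- small_perception_trials(seed = 45)
  tr <- px$trials
  tr$perception_rating <- 50
  expect_error(fit_perception(tr[1:6, ], "M5"), "at least 8")
  tr2 <- tr
  tr2$expectation <- NULL
  expect_error(fit_perception(tr2, "M2"), "expectation")
  tr3 <- tr
  tr3$calib <- NULL
  expect_error(fit_perception(tr3, "M2"), "calibration")
  f <- fit_perception(tr3, "M2", calibration = px$calibration)
  expect_s3_class(f, "perception_fit")
})
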