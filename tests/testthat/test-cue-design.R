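# Factorial design enumeration and constrained cue generation.

test_that("design enumeration reproduces the factorial trial arithmetic", {
  cases <- list(
    expectation = list(n = 360L, cells = 60L, blocks = 6L,
                       cell_cols = c("modality", "cue_mean_level",
                                     "cue_sd_level", "cue_skew_level")),
    cued_perception = list(n = 144L, cells = 48L, blocks = 6L,
                           cell_cols = c("modality", "intensity_level",
                                         "cue_mean_level", "cue_sd_level",
                                         "cue_skew_level")),
    stimulus_response = list(n = 50L, cells = 10L, blocks = 2L,
                             cell_cols = c("modality", "intensity_level")))
  for (task in names(cases)) {
    cs <- cases[[task]]
    d <- enumerate_design(task, seed = 7)
    expect_identical(nrow(d), cs$n)
    key <- do.call(paste, d[cs$cell_cols])
    expect_identical(length(unique(key)), cs$cells)
    # exhaustive and non-redundant: every cell equally often
    expect_true(all(table(key) == cs$n / cs$cells))
    expect_identical(sort(unique(d$block)), seq_len(cs$blocks))
  }
})

test_that("each task's block structure matches the paradigm", {
  d <- enumerate_design("expectation", seed = 3)
  # 3 consecutive single-modality blocks per modality
  mod_by_block <- vapply(split(d$modality, d$block),
                         function(x) unique(x), "")
  expect_length(unique(mod_by_block[1:3]), 1L)
  expect_length(unique(mod_by_block[4:6]), 1L)
  expect_setequal(unique(mod_by_block), c("pain", "vision"))

  cp <- enumerate_design("cued_perception", seed = 3)
  for (b in 1:6) {
    bl <- cp[cp$block == b, ]
    expect_identical(nrow(bl), 24L)
    # two single-modality mini-blocks of 12 trials
    tab <- table(bl$mini_block, bl$modality)
    expect_true(all(rowSums(tab) == 12L))
    expect_true(all(apply(tab, 1L, function(r) sum(r > 0)) == 1L))
  }
  sr <- enumerate_design("stimulus_response", seed = 3)
  expect_true(all(table(sr$modality) == 25L))
  expect_true(all(table(sr$modality, sr$intensity_level) == 5L))
})

test_that("unknown task names are rejected with the valid options", {
  expect_error(enumerate_design("perception"), "valid tasks")
  expect_error(enumerate_design(c("expectation", "expectation")),
               "valid tasks")
})

test_that("design enumeration is reproducible under a fixed seed", {
  expect_identical(enumerate_design("cued_perception", seed = 11),
                   enumerate_design("cued_perception", seed = 11))
  expect_false(identical(enumerate_design("cued_perception", seed = 11),
                         enumerate_design("cued_perception", seed = 12)))
})

test_that("sample skewness is the adjusted Fisher-Pearson G1", {
  # exactly symmetric paired deviations around the mean
  sym <- c(50 + c(-20, -12, -7, -3, -1), 50 + c(20, 12, 7, 3, 1))
  expect_equal(sample_skewness(sym), 0)
  expect_gt(sample_skewness(c(1, 1, 1, 1, 10)), 0)
  # frozen value computed independently from the G1 formula
  x <- c(30, 35, 40, 45, 50, 55, 60, 65, 70, 95)
  expect_equal(sample_skewness(x), 0.888191942843035, tolerance = 1e-12)
  skip_if_not_installed("e1071")
  expect_equal(sample_skewness(x), e1071::skewness(x, type = 2),
               tolerance = 1e-12)
  expect_error(sample_skewness(rep(4, 10)), "zero-variance")
  expect_error(sample_skewness(c(1, 2)), "at least 3")
})

test_that("generated cues satisfy every distributional constraint", {
  cells <- expand.grid(mean = c(30, 50, 70), sd = c(5, 12.5),
                       skew = c("negative", "symmetric", "positive"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    b <- distcue:::.generate_cue_batch(60L, cl$mean, cl$sd, cl$skew)
    v <- b$values
    expect_true(all(v >= 0 & v <= 100))
    expect_equal(rowMeans(v), rep(cl$mean, 60L), tolerance = 1e-8)
    expect_equal(apply(v, 1, sd), rep(cl$sd, 60L), tolerance = 1e-8)
    g <- apply(v, 1, sample_skewness)
    if (cl$skew == "symmetric") {
      expect_true(all(abs(g) <= 0.035))
    } else {
      if (cl$skew == "positive") expect_true(all(g > 0.3))
      else expect_true(all(g < -0.3))
      # injected extreme element 2.0-2.5 realized SDs from the realized mean
      d <- (v[, 10] - rowMeans(v)) / apply(v, 1, sd)
      if (cl$skew == "negative") d <- -d
      expect_true(all(d >= 2.0 & d <= 2.5))
      expect_equal(abs(d), b$extreme_d, tolerance = 1e-8)
    }
  }
})

test_that("single-cue generation is reproducible and validates its spec", {
  sp <- cue_spec("pain", 70, 12.5, "positive")
  c1 <- generate_cue(sp, seed = 5)
  c2 <- generate_cue(sp, seed = 5)
  expect_identical(c1$values, c2$values)
  expect_equal(c1$realized_mean, 70)
  expect_equal(c1$realized_sd, 12.5)
  expect_gt(c1$realized_skew, 0.3)
  expect_identical(c1$extreme_index, 10L)
  expect_error(cue_spec("pain", 45, 5, "symmetric"), "mean_target")
  expect_error(cue_spec("pain", 30, -1, "symmetric"), "sd_target")
  expect_error(cue_spec("audio", 30, 5, "symmetric"), "modality")
  expect_error(cue_spec("pain", 30, 5, "flat"), "skew_level")
  # perception task restricts the mean set further
  expect_error(cue_spec("pain", 50, 5, "symmetric", task = "cued_perception"),
               "mean_target")
})

test_that("near-zero target SD yields a near-constant cue, not an error", {
  cue <- generate_cue(cue_spec("vision", 50, 1e-4, "symmetric"), seed = 1,
                      max_attempts = 1e5)
  expect_equal(sd(cue$values), 1e-4, tolerance = 1e-10)
  expect_equal(mean(cue$values), 50, tolerance = 1e-10)
  expect_error(distcue:::.generate_cue_batch(1L, 50, 0, "symmetric"),
               "positive")
})

test_that("cue generation attaches values to every cue trial of a design", {
  des <- cached_cue_design(31)
  v <- cue_values(des)
  expect_false(anyNA(v))
  expect_equal(rowMeans(v), des$cue_mean_level, tolerance = 1e-8)
  expect_equal(apply(v, 1, sd), des$cue_sd_level, tolerance = 1e-8)
  sr <- generate_cues(enumerate_design("stimulus_response", seed = 1),
                      seed = 2)
  expect_true(all(is.na(sr$cue_v1)))
})

test_that("design factors are uncorrelated across generated trials", {
  des <- cached_cue_design(31)
  num <- cbind(mean = des$cue_mean_level, sd = des$cue_sd_level,
               skew = match(des$cue_skew_level, .skew_levels <-
                              c("negative", "symmetric", "positive")) - 2)
  cc <- cor(num)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.1))
})
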