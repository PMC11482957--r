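# shared fixtures built in code at test time

# a reusable expectation design with cues, one per (seed) request
cached_cue_design <- local({
  cache <- list()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_cues(enumerate_design("expectation",
                                                      seed = seed),
                                     seed = seed + 1)
    cache[[key]]
  }
})

cue_values <- function(trials) as.matrix(trials[, paste0("cue_v", 1:10)])

# noiseless expectation ratings generated at known (k, b)
with_expect_ratings <- function(trials, k, b, noise_sd = 0) {
  pred <- predict_expectation(cue_values(trials), k, b)
  trials$expectation_rating <- pmin(pmax(
    pred + stats::rnorm(nrow(trials), 0, noise_sd), 0), 100)
  trials
}

# minimal single-participant cued-perception table with calibration attached
small_perception_trials <- function(seed = 1, k = 1.66, b = -1.64) {
  des <- generate_cues(enumerate_design("cued_perception", seed = seed),
                       seed = seed + 1)
  des <- cbind(participant = 1L, des)
  calib <- data.frame(participant = 1L,
                      modality = rep(c("pain", "vision"), each = 2),
                      intensity_level = c(2, 4, 2, 4),
                      calib_mean = c(35, 60, 30, 70))
  des <- attach_calibration(des, calib)
  des$expectation <- predict_expectation(cue_values(des), k, b)
  list(trials = des, calibration = calib)
}
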