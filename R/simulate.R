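# Synthetic-cohort generation: complete participants with known parameters.

#' Configuration of a synthetic cohort
#'
#' Holds the truth-sampling distributions and design constants used by
#' [simulate_cohort()]. Defaults reproduce the study conditions: 45
#' participants, trial-level Gaussian rating noise of SD 6 VAS units, and
#' per-modality weighting-parameter distributions centred on the observed
#' group medians (`k`: log-normal around 1.66 for pain and 1.47 for vision;
#' `b`: normal around -1.64 for pain and 0.16 for vision).
#'
#' @param n_participants Number of synthetic participants (>= 2).
#' @param seed Integer master seed; all stages draw from named substreams.
#' @param k_center Median of the log-normal truth distribution of `k`, per
#'   modality.
#' @param k_sdlog SD of `log(k)` across participants.
#' @param b_center,b_sd Mean and SD of the normal truth distribution of `b`.
#' @param noise_sd Trial-level rating noise SD (VAS units), all tasks.
#' @param calib_intercept,calib_slope Population mean intercept/slope (VAS
#'   units per intensity level) of the stimulus-response function, per
#'   modality.
#' @param calib_intercept_sd,calib_slope_sd Between-participant SDs of the
#'   calibration intercept and slope.
#' @param perception_model Generating observer model per participant
#'   (recycled to `n_participants`); any of `"M1"`..`"M5"`.
#' @param s_range,w_range,alpha_range Uniform truth-sampling ranges for the
#'   observer-model scaling factors, cue weights and learning rates.
#' @param rt_meanlog,rt_sdlog Log-normal response-time law (seconds) for
#'   in-window responses.
#' @param rt_outlier_frac Fraction of trials whose response time falls
#'   outside the valid 0.2-4.5 s rating window (split evenly between
#'   too-fast and too-slow), emulating the observed exclusion rate.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 45, seed = 1,
                          k_center = c(pain = 1.66, vision = 1.47),
                          k_sdlog = 0.35,
                          b_center = c(pain = -1.64, vision = 0.16),
                          b_sd = 2,
                          noise_sd = 6,
                          calib_intercept = c(pain = 10, vision = 8),
                          calib_slope = c(pain = 12, vision = 16),
                          calib_intercept_sd = 4, calib_slope_sd = 1.5,
                          perception_model = "M2",
                          s_range = c(0.8, 1.2),
                          w_range = c(0.2, 0.8),
                          alpha_range = c(-0.3, 0.3),
                          rt_meanlog = log(1.1), rt_sdlog = 0.3,
                          rt_outlier_frac = 0.036) {
  stopifnot(n_participants >= 2, noise_sd >= 0,
            all(perception_model %in% .perception_models))
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d participants, seed %s, rating noise SD %g\n",
              x$n_participants, format(x$seed), x$noise_sd))
  cat(sprintf("  k ~ logN(median %s), b ~ N(%s, sd %g)\n",
              paste(sprintf("%s %.2f", names(x$k_center), x$k_center),
                    collapse = " / "),
              paste(sprintf("%s %.2f", names(x$b_center), x$b_center),
                    collapse = " / "), x$b_sd))
  cat("  generating perception model(s):",
      paste(unique(x$perception_model), collapse = ", "), "\n")
  invisible(x)
}

#' Sample generative participant truths from a cohort configuration
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per participant: weighting parameters
#'   per modality, the generating observer model and its parameters, and
#'   the calibration slopes/intercepts.
#' @export
sample_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  .with_seed(.substream(config$seed, 1), {
    data.frame(
      participant = seq_len(n),
      k_pain = stats::rlnorm(n, log(config$k_center[["pain"]]),
                             config$k_sdlog),
      k_vision = stats::rlnorm(n, log(config$k_center[["vision"]]),
                               config$k_sdlog),
      b_pain = stats::rnorm(n, config$b_center[["pain"]], config$b_sd),
      b_vision = stats::rnorm(n, config$b_center[["vision"]], config$b_sd),
      model = rep(config$perception_model, length.out = n),
      s_p = stats::runif(n, config$s_range[1L], config$s_range[2L]),
      s_v = stats::runif(n, config$s_range[1L], config$s_range[2L]),
      w = stats::runif(n, config$w_range[1L], config$w_range[2L]),
      w_p = stats::runif(n, config$w_range[1L], config$w_range[2L]),
      w_v = stats::runif(n, config$w_range[1L], config$w_range[2L]),
      alpha = stats::runif(n, config$alpha_range[1L], config$alpha_range[2L]),
      alpha_p = stats::runif(n, config$alpha_range[1L],
                             config$alpha_range[2L]),
      alpha_v = stats::runif(n, config$alpha_range[1L],
                             config$alpha_range[2L]),
      calib_icpt_pain = stats::rnorm(n, config$calib_intercept[["pain"]],
                                     config$calib_intercept_sd),
      calib_icpt_vision = stats::rnorm(n, config$calib_intercept[["vision"]],
                                       config$calib_intercept_sd),
      calib_slope_pain = stats::rnorm(n, config$calib_slope[["pain"]],
                                      config$calib_slope_sd),
      calib_slope_vision = stats::rnorm(n, config$calib_slope[["vision"]],
                                        config$calib_slope_sd),
      stringsAsFactors = FALSE)
  })
}

# truth row -> perception_params object
.truth_params <- function(tr) {
  switch(tr$model,
    M1 = perception_params("M1", s_p = tr$s_p, s_v = tr$s_v),
    M2 = perception_params("M2", s_p = tr$s_p, s_v = tr$s_v, w = tr$w),
    M3 = perception_params("M3", s_p = tr$s_p, s_v = tr$s_v, w0 = tr$w,
                           alpha = tr$alpha),
    M4 = perception_params("M4", s_p = tr$s_p, s_v = tr$s_v, w_p = tr$w_p,
                           w_v = tr$w_v),
    M5 = perception_params("M5", s_p = tr$s_p, s_v = tr$s_v, w0_p = tr$w_p,
                           w0_v = tr$w_v, alpha_p = tr$alpha_p,
                           alpha_v = tr$alpha_v))
}

# response times: log-normal in-window draws plus an exact outlier mixture
# strictly outside the 0.2-4.5 s rating window
.simulate_rt <- function(n, meanlog, sdlog, outlier_frac) {
  u <- stats::runif(n)
  fast <- u < outlier_frac / 2
  slow <- !fast & u < outlier_frac
  rt <- numeric(n)
  rt[fast] <- stats::runif(sum(fast), 0.02, 0.199)
  rt[slow] <- stats::runif(sum(slow), 4.501, 8)
  ok <- !(fast | slow)
  r <- stats::rlnorm(sum(ok), meanlog, sdlog)
  bad <- r < 0.2 | r > 4.5
  while (any(bad)) {
    r[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    bad <- r < 0.2 | r > 4.5
  }
  rt[ok] <- r
  rt
}

#' Simulate the stimulus-response (calibration) task
#'
#' Each trial's rating is a participant- and modality-specific affine
#' function of the stimulus intensity level plus Gaussian noise, clipped to
#' the 0-100 scale; cell means are aggregated into a calibration table.
#'
#' @param truth Data frame from [sample_truth()].
#' @param config The [cohort_config()] (noise SD, RT law).
#' @param seed Optional integer seed.
#' @return List with `trials` (raw calibration trials including `rating`
#'   and `response_time_s`) and `calibration` (a [calibration_table()]).
#' @export
simulate_calibration <- function(truth, config, seed = NULL) {
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      des <- enumerate_design("stimulus_response")
      icpt <- ifelse(des$modality == "pain", tr$calib_icpt_pain,
                     tr$calib_icpt_vision)
      slope <- ifelse(des$modality == "pain", tr$calib_slope_pain,
                      tr$calib_slope_vision)
      des$rating <- .clamp(icpt + slope * des$intensity_level +
                             stats::rnorm(nrow(des), 0, config$noise_sd),
                           0, 100)
      des$response_time_s <- .simulate_rt(nrow(des), config$rt_meanlog,
                                          config$rt_sdlog,
                                          config$rt_outlier_frac)
      cbind(participant = tr$participant, des)
    })
    trials <- do.call(rbind, rows)
    rownames(trials) <- NULL
    list(trials = trials, calibration = calibration_table(trials))
  })
}

#' Simulate the expectation task of a synthetic cohort
#'
#' Generates each participant's randomized expectation design with fresh
#' constrained cue distributions, computes model expectations under the
#' participant's true `(k, b)` per modality, adds Gaussian rating noise
#' (clipped to 0-100) and draws response times.
#'
#' @inheritParams simulate_calibration
#' @return Trial table with cue columns, `expectation_true` (noiseless
#'   model expectation), `expectation_rating` and `response_time_s`.
#' @export
simulate_expectation_task <- function(truth, config, seed = NULL) {
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      des <- generate_cues(enumerate_design("expectation"))
      v <- .cue_matrix(des)
      pred <- numeric(nrow(des))
      for (m in .modalities) {
        sel <- des$modality == m
        pred[sel] <- .predict_expectation_mat(
          v[sel, , drop = FALSE],
          if (m == "pain") tr$k_pain else tr$k_vision,
          if (m == "pain") tr$b_pain else tr$b_vision)
      }
      des$expectation_true <- pred
      des$expectation_rating <- .clamp(
        pred + stats::rnorm(nrow(des), 0, config$noise_sd), 0, 100)
      des$response_time_s <- .simulate_rt(nrow(des), config$rt_meanlog,
                                          config$rt_sdlog,
                                          config$rt_outlier_frac)
      cbind(participant = tr$participant, des)
    })
    trials <- do.call(rbind, rows)
    rownames(trials) <- NULL
    trials
  })
}

#' Simulate the cued-perception task of a synthetic cohort
#'
#' Each participant's trials are generated from their true observer model:
#' static models add Gaussian noise to the model prediction; learning
#' models propagate the cue weight with realized (noisy, clipped) ratings
#' via [run_learning()]'s simulate mode, preserving presentation order.
#' Trial-level expectations come from the participant's true `(k, b)`.
#'
#' @inheritParams simulate_calibration
#' @param calibration A [calibration_table()] (typically from
#'   [simulate_calibration()]).
#' @return Trial table with cue columns, `calib`, `expectation` (true-
#'   parameter cue-based expectation), `perception_rating`, `w_true`
#'   (learning models) and `response_time_s`.
#' @export
simulate_perception_task <- function(truth, config, calibration,
                                     seed = NULL) {
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      if (!tr$model %in% .perception_models)
        stop("unknown generating model: ", tr$model)
      des <- generate_cues(enumerate_design("cued_perception"))
      des <- cbind(participant = tr$participant, des)
      v <- .cue_matrix(des)
      expv <- numeric(nrow(des))
      for (m in .modalities) {
        sel <- des$modality == m
        expv[sel] <- .predict_expectation_mat(
          v[sel, , drop = FALSE],
          if (m == "pain") tr$k_pain else tr$k_vision,
          if (m == "pain") tr$b_pain else tr$b_vision)
      }
      des$expectation <- expv
      des <- attach_calibration(des, calibration)
      pars <- .truth_params(tr)
      if (tr$model %in% c("M3", "M5")) {
        sim <- run_learning(des, pars, mode = "simulate",
                            noise_sd = config$noise_sd)
        des$perception_rating <- sim$ratings
        des$w_true <- sim$w
      } else {
        pred <- predict_perception(des, pars)
        des$perception_rating <- .clamp(
          pred + stats::rnorm(nrow(des), 0, config$noise_sd), 0, 100)
        des$w_true <- NA_real_
      }
      des$response_time_s <- .simulate_rt(nrow(des), config$rt_meanlog,
                                          config$rt_sdlog,
                                          config$rt_outlier_frac)
      des
    })
    trials <- do.call(rbind, rows)
    rownames(trials) <- NULL
    trials
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [sample_truth()], [simulate_calibration()],
#' [simulate_expectation_task()] and [simulate_perception_task()] under
#' named substreams of the configuration seed, so the whole cohort is
#' reproducible from `config$seed` alone.
#'
#' @param config A [cohort_config()].
#' @return List with `truth`, `calibration_trials`, `calibration`,
#'   `expectation_trials`, `perception_trials`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- sample_truth(config)
  cal <- simulate_calibration(truth, config, seed = .substream(config$seed, 2))
  exp_trials <- simulate_expectation_task(truth, config,
                                          seed = .substream(config$seed, 3))
  per_trials <- simulate_perception_task(truth, config, cal$calibration,
                                         seed = .substream(config$seed, 4))
  list(truth = truth, calibration_trials = cal$trials,
       calibration = cal$calibration, expectation_trials = exp_trials,
       perception_trials = per_trials, config = config)
}

#' Exclude trials with invalid response times
#'
#' Removes trials rated too fast to be deliberate (RT < 0.2 s) or not
#' completed within the 4.5 s rating period (RT > 4.5 s). Boundary values
#' exactly 0.2 or 4.5 s are kept (the exclusion inequalities are strict).
#'
#' @param trials Trial table with a `response_time_s` column.
#' @return List with `trials` (the kept rows) and `log`, a per-participant
#'   data frame of exclusion counts by reason.
#' @export
exclude_trials <- function(trials) {
  .require_cols(trials, "response_time_s")
  rt <- trials$response_time_s
  too_fast <- rt < 0.2
  too_slow <- rt > 4.5
  keep <- !(too_fast | too_slow)
  part <- if (!is.null(trials$participant)) trials$participant
          else rep(1L, nrow(trials))
  log <- do.call(rbind, lapply(split(seq_len(nrow(trials)), part),
    function(ii) data.frame(
      participant = part[ii[1L]],
      n_total = length(ii),
      n_too_fast = sum(too_fast[ii]),
      n_too_slow = sum(too_slow[ii]),
      n_kept = sum(keep[ii]), stringsAsFactors = FALSE)))
  rownames(log) <- NULL
  list(trials = trials[keep, , drop = FALSE], log = log)
}
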