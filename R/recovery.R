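# Parameter-recovery and model-identification studies on synthetic cohorts.

#' Run a full parameter-recovery study on a synthetic cohort
#'
#' Simulates a cohort from known truths, applies the response-time
#' exclusion rule, fits the expectation model per participant x modality,
#' runs the group tests, fits the requested observer models (with
#' trial-level expectations from each participant's *fitted* `(k, b)` by
#' default) and compares them. Reports agreement between true and
#' recovered parameters and the model-identification confusion matrix.
#'
#' @param config A [cohort_config()].
#' @param models Observer models to fit (default all five).
#' @param use_true_expectation If `TRUE`, perception fitting uses each
#'   participant's generating `(k, b)` instead of the fitted values
#'   (sensitivity analysis).
#' @param ... Passed to [fit_perception()] via [fit_perception_cohort()].
#' @return Object of class `recovery_report` with elements `cohort`
#'   (the simulated data), `expectation_fits`, `group_tests`,
#'   `expectation_recovery` (per modality: Spearman/Pearson correlation,
#'   bias, RMSE for `k` and `b`), `perception_fits`, `comparison`,
#'   `w_recovery` (for static-weight truths: true vs fitted cue weight) and
#'   `confusion` (generating model x AIC winner).
#' @export
recovery_study <- function(config, models = c("M1", "M2", "M3", "M4", "M5"),
                           use_true_expectation = FALSE, ...) {
  cohort <- simulate_cohort(config)
  exp_kept <- exclude_trials(cohort$expectation_trials)
  per_kept <- exclude_trials(cohort$perception_trials)
  efits <- fit_expectation_cohort(exp_kept$trials)
  gt <- expectation_group_tests(efits)
  truth <- cohort$truth
  erec <- lapply(.modalities, function(m) {
    fm <- efits[efits$modality == m, ]
    fm <- fm[order(fm$participant), ]
    tk <- if (m == "pain") truth$k_pain else truth$k_vision
    tb <- if (m == "pain") truth$b_pain else truth$b_vision
    ord <- match(fm$participant, truth$participant)
    list(
      k = .recovery_stats(tk[ord], fm$k),
      b = .recovery_stats(tb[ord], fm$b))
  })
  names(erec) <- .modalities
  per_trials <- per_kept$trials
  if (use_true_expectation) {
    # expectation column already carries the true-parameter expectations
    pfits <- fit_perception_cohort(per_trials, cohort$calibration,
                                   models = models, ...)
  } else {
    per_trials$expectation <- expectation_from_fits(per_trials, efits)
    pfits <- fit_perception_cohort(per_trials, cohort$calibration,
                                   models = models, ...)
  }
  comparison <- if (length(models) >= 2L)
    compare_perception_models(pfits) else NULL
  ids <- attr(pfits, "participants")
  confusion <- NULL
  if (!is.null(comparison)) {
    aic_mat <- vapply(names(pfits), function(m)
      vapply(pfits[[m]], function(f) f$aic, 0), numeric(length(ids)))
    if (is.null(dim(aic_mat))) aic_mat <- matrix(aic_mat, nrow = 1L,
                                                 dimnames = list(NULL,
                                                                 names(pfits)))
    winner <- colnames(aic_mat)[apply(aic_mat, 1L, which.min)]
    gen <- truth$model[match(ids, truth$participant)]
    confusion <- table(generated = factor(gen, levels = names(pfits)),
                       winner = factor(winner, levels = names(pfits)))
  }
  w_recovery <- NULL
  if ("M2" %in% names(pfits)) {
    sel <- truth$model[match(ids, truth$participant)] == "M2"
    if (any(sel)) {
      w_hat <- vapply(pfits[["M2"]], function(f) f$params[["w"]], 0)[sel]
      w_true <- truth$w[match(ids, truth$participant)][sel]
      w_recovery <- .recovery_stats(w_true, w_hat)
    }
  }
  structure(list(cohort = cohort, exclusion_logs = list(
                   expectation = exp_kept$log, perception = per_kept$log),
                 expectation_fits = efits, group_tests = gt,
                 expectation_recovery = erec, perception_fits = pfits,
                 comparison = comparison, w_recovery = w_recovery,
                 confusion = confusion),
            class = "recovery_report")
}

.recovery_stats <- function(true, est) {
  list(spearman = suppressWarnings(
         stats::cor(true, est, method = "spearman")),
       pearson = suppressWarnings(stats::cor(true, est)),
       bias = mean(est - true),
       rmse = sqrt(mean((est - true)^2)),
       n = length(true))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Synthetic-cohort recovery study\n")
  for (m in names(x$expectation_recovery)) {
    r <- x$expectation_recovery[[m]]
    cat(sprintf("  %s: k Spearman %.3f (bias %+.3f), b Spearman %.3f (bias %+.3f)\n",
                m, r$k$spearman, r$k$bias, r$b$spearman, r$b$bias))
  }
  if (!is.null(x$w_recovery))
    cat(sprintf("  M2 cue weight w: bias %+.4f, RMSE %.4f (n = %d)\n",
                x$w_recovery$bias, x$w_recovery$rmse, x$w_recovery$n))
  if (!is.null(x$confusion)) {
    cat("\nModel identification (generating model x AIC winner):\n")
    print(x$confusion)
  }
  invisible(x)
}
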