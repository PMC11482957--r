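#' Rescale cue values to the unit range and demean
#'
#' Divides the ten VAS cue values by the 100-point scale range and subtracts
#' their mean, so that values below the cue mean are negative and values
#' above are positive. These deviations are the input of the weighting
#' model.
#'
#' @param values Numeric vector of cue values on the 0-100 VAS.
#' @return Numeric vector of zero-sum deviations.
#' @export
rescale_demean <- function(values) {
  x <- values / 100
  x - mean(x)
}

#' Power-term weights: inlier vs outlier weighting
#'
#' Raw weight of deviation `x_i` is `|x_i|^(k-1)` (with `|x_i|` floored at
#' `eps` to avoid `0^0` at small `k`), normalized to sum to one. `k = 1`
#' weights all values equally; `k > 1` over-weights outliers (values far
#' from the cue mean); `k < 1` over-weights inliers. Evaluated in log space
#' so that extreme `k` neither overflows nor underflows.
#'
#' @param x Deviations from [rescale_demean()].
#' @param k Power parameter, in (0, 1000].
#' @param eps Floor on `|x_i|` before exponentiation.
#' @return Nonnegative weights summing to 1.
#' @export
power_weights <- function(x, k, eps = 1e-6) {
  if (!(k > 0 && k <= 1000)) stop("k must lie in (0, 1000]")
  la <- (k - 1) * log(pmax(abs(x), eps))
  w <- exp(la - max(la))
  w / sum(w)
}

#' Logistic weights: below- vs above-mean weighting
#'
#' `w_i = 1 / (1 + exp(-b * x_i))`. `b = 0` gives 0.5 everywhere; `b < 0`
#' over-weights values below the cue mean, `b > 0` values above it.
#'
#' @param x Deviations from [rescale_demean()].
#' @param b Logistic parameter, in \[-1000, 1000\].
#' @return Weights in \[0, 1\].
#' @export
logistic_weights <- function(x, b) {
  if (!(b >= -1000 && b <= 1000)) stop("b must lie in [-1000, 1000]")
  stats::plogis(b * x)
}

#' Combine power and logistic weights into a probability vector
#'
#' @param w_power Output of [power_weights()].
#' @param w_logistic Output of [logistic_weights()] for the same cue.
#' @return Nonnegative weights summing to 1.
#' @export
combine_weights <- function(w_power, w_logistic) {
  s <- w_power + w_logistic
  tot <- sum(s)
  stopifnot(tot > 0)
  s / tot
}

#' Combined cue-value weights for one cue
#'
#' @inheritParams power_weights
#' @inheritParams logistic_weights
#' @param values Cue values on the 0-100 VAS.
#' @return The ten combined, normalized weights.
#' @export
cue_weights <- function(values, k, b, eps = 1e-6) {
  x <- rescale_demean(values)
  combine_weights(power_weights(x, k, eps), logistic_weights(x, b))
}

#' Model-predicted expectation for one or many cues
#'
#' The predicted expectation is the weighted sum of the original cue values,
#' with weights from the combined power/logistic distortion. It is a convex
#' combination, so predictions always lie within the range of the cue
#' values.
#'
#' @param values A length-10 numeric vector, or an `n x 10` matrix /
#'   data frame of cue values (one cue per row).
#' @param k,b Weighting parameters.
#' @param eps Floor on `|x_i|` in the power term.
#' @return A scalar (vector input) or length-`n` vector of predicted VAS
#'   expectations.
#' @examples
#' v <- c(30, 35, 40, 45, 50, 55, 60, 65, 70, 95)
#' predict_expectation(v, k = 1, b = 0)  # equals mean(v)
#' @export
predict_expectation <- function(values, k, b, eps = 1e-6) {
  if (is.matrix(values) || is.data.frame(values))
    return(.predict_expectation_mat(as.matrix(values), k, b, eps))
  sum(values * cue_weights(values, k, b, eps))
}

.predict_expectation_mat <- function(v, k, b, eps = 1e-6) {
  x <- v / 100
  x <- x - rowMeans(x)
  la <- log(pmax(abs(x), eps))
  p <- (k - 1) * la
  p <- p - .row_max(p)
  wk <- exp(p)
  wk <- wk / rowSums(wk)
  s <- wk + stats::plogis(b * x)
  w <- s / rowSums(s)
  unname(rowSums(v * w))
}

#' Fit the cue-value weighting model of expectation generation
#'
#' Estimates the distortion parameters `(k, b)` for a single participant and
#' modality by bounded nonlinear least squares on the trial-level
#' expectation ratings, with a multi-start grid to guard against local
#' minima.
#'
#' @param trials Data frame with cue columns `cue_v1..cue_v10` and an
#'   `expectation_rating` column; at least 10 trials from one participant
#'   and modality.
#' @param init_grid Named list of start values; the Cartesian product of
#'   `init_grid$k` and `init_grid$b` is used.
#' @param bounds Named list of `c(lower, upper)` box constraints for `k`
#'   (default `(1e-6, 1000]`) and `b` (default `[-1000, 1000]`).
#' @param tol Convergence tolerance on the residual sum of squares passed to
#'   the L-BFGS-B optimizer.
#' @param eps Floor on `|x_i|` in the power term.
#' @return An object of class `expectation_fit` with components `params`
#'   (`k`, `b`), `rss`, `pearson_r`, `rmse` (`sqrt(rss / n)`), `n_trials`,
#'   `converged`, `fitted`, `observed` and `multistart_log`.
#' @seealso [predict.expectation_fit()], [expectation_group_tests()]
#' @export
fit_expectation <- function(trials,
                            init_grid = list(k = c(0.3, 1, 2, 5),
                                             b = c(-8, 0, 8)),
                            bounds = list(k = c(1e-6, 1000),
                                          b = c(-1000, 1000)),
                            tol = 1e-10, eps = 1e-6) {
  .require_cols(trials, "expectation_rating")
  v <- .cue_matrix(trials)
  y <- trials$expectation_rating
  keep <- stats::complete.cases(v) & is.finite(y)
  v <- v[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(v)
  if (n < 10L) stop("fit_expectation needs at least 10 complete trials")
  x <- v / 100
  x <- x - rowMeans(x)
  la <- log(pmax(abs(x), eps))
  obj <- function(par) .expectation_rss_cpp(par[1L], par[2L], x, la, v, y)
  starts <- expand.grid(k = init_grid$k, b = init_grid$b,
                        KEEP.OUT.ATTRS = FALSE)
  lower <- c(bounds$k[1L], bounds$b[1L])
  upper <- c(bounds$k[2L], bounds$b[2L])
  ctl <- list(factr = max(tol / .Machine$double.eps, 1))
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      stats::optim(c(starts$k[i], starts$b[i]), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctl),
      error = function(e) e)
  }
  ok <- !vapply(runs, inherits, logical(1L), "error")
  if (!any(ok)) {
    msgs <- unique(vapply(runs, conditionMessage, character(1L)))
    stop("all optimizer starts failed: ", paste(msgs, collapse = "; "))
  }
  log_df <- data.frame(
    k_start = starts$k, b_start = starts$b,
    k = vapply(seq_along(runs), function(i)
      if (ok[i]) runs[[i]]$par[1L] else NA_real_, 0),
    b = vapply(seq_along(runs), function(i)
      if (ok[i]) runs[[i]]$par[2L] else NA_real_, 0),
    rss = vapply(seq_along(runs), function(i)
      if (ok[i]) runs[[i]]$value else NA_real_, 0),
    convergence = vapply(seq_along(runs), function(i)
      if (ok[i]) runs[[i]]$convergence else NA_integer_, 0L))
  best_i <- which.min(log_df$rss)
  best <- runs[[best_i]]
  pred <- .predict_expectation_mat(v, best$par[1L], best$par[2L], eps)
  rss <- best$value
  structure(list(
    params = c(k = unname(best$par[1L]), b = unname(best$par[2L])),
    rss = rss,
    pearson_r = suppressWarnings(stats::cor(pred, y)),
    rmse = sqrt(rss / n),
    n_trials = n,
    converged = best$convergence == 0L,
    fitted = pred, observed = y,
    multistart_log = log_df,
    eps = eps,
    call = match.call()),
    class = "expectation_fit")
}

#' @export
print.expectation_fit <- function(x, ...) {
  cat("Cue-value weighting model of expectation generation\n")
  cat(sprintf("  k = %.4f (outlier weighting; 1 = equal)\n", x$params["k"]))
  cat(sprintf("  b = %.4f (below/above-mean weighting; 0 = equal)\n",
              x$params["b"]))
  cat(sprintf("  n = %d trials, RSS = %.3f, RMSE = %.3f, Pearson r = %.3f\n",
              x$n_trials, x$rss, x$rmse, x$pearson_r))
  if (!x$converged) cat("  warning: best start did not report convergence\n")
  invisible(x)
}

#' @export
coef.expectation_fit <- function(object, ...) object$params

#' @export
fitted.expectation_fit <- function(object, ...) object$fitted

#' @export
residuals.expectation_fit <- function(object, ...)
  object$observed - object$fitted

#' Predict expectations for new cues from a fitted model
#'
#' @param object An `expectation_fit`.
#' @param newdata Data frame with `cue_v1..cue_v10` columns or an `n x 10`
#'   matrix of cue values. Defaults to the fitted values.
#' @param ... Unused.
#' @return Predicted VAS expectations.
#' @export
predict.expectation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  v <- if (is.matrix(newdata)) newdata else .cue_matrix(newdata)
  .predict_expectation_mat(v, object$params["k"], object$params["b"],
                           object$eps)
}

#' Plot observed against model-predicted expectation ratings
#'
#' @param x An `expectation_fit`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.expectation_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$observed,
                 xlab = "predicted expectation (VAS)",
                 ylab = "observed expectation (VAS)",
                 main = sprintf("k = %.2f, b = %.2f, r = %.3f",
                                x$params["k"], x$params["b"], x$pearson_r),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
summary.expectation_fit <- function(object, ...) {
  print(object)
  cat("\nMulti-start log:\n")
  print(object$multistart_log, row.names = FALSE)
  invisible(object)
}

#' Fit the expectation model for every participant x modality
#'
#' @param trials Trial table with `participant`, `modality`,
#'   `cue_v1..cue_v10` and `expectation_rating` columns.
#' @param ... Passed to [fit_expectation()].
#' @return Data frame with one row per participant x modality: `k`, `b`,
#'   `rss`, `r`, `rmse`, `n`, `converged`.
#' @export
fit_expectation_cohort <- function(trials, ...) {
  .require_cols(trials, c("participant", "modality", "expectation_rating"))
  groups <- split(trials,
                  list(trials$participant, trials$modality), drop = TRUE)
  rows <- lapply(groups, function(g) {
    f <- fit_expectation(g, ...)
    data.frame(participant = g$participant[1L], modality = g$modality[1L],
               k = f$params[["k"]], b = f$params[["b"]], rss = f$rss,
               r = f$pearson_r, rmse = f$rmse, n = f$n_trials,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant, out$modality), , drop = FALSE]
}
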