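# Five nested observer models of cued perception.
#
# All models share the "intensity" term: each participant's mean rating for
# the trial's modality x stimulus intensity in the stimulus-response task,
# scaled by a free modality-specific factor s in [0, 5].
#   M1: rating = intensity * s                       (s_p, s_v)
#   M2: rating = (1-w) * intensity * s + w * expectation, global w in [0,1]
#   M3: as M2, but w(t) is updated by prediction errors with rate alpha
#   M4: as M2 with modality-specific w_p, w_v
#   M5: as M3 with modality-specific (w0, alpha) per modality
# Prediction errors are computed on a 0-1 scale: PE = (rating - expectation)/100,
# and w is clamped to [0, 1] after each update.

.perception_models <- c("M1", "M2", "M3", "M4", "M5")

#' Free parameters of a perception model
#'
#' @param model One of `"M1"`..`"M5"`.
#' @return Character vector of parameter names (length 2/3/4/4/6 for
#'   M1/M2/M3/M4/M5).
#' @export
perception_param_names <- function(model) {
  switch(match.arg(model, .perception_models),
         M1 = c("s_p", "s_v"),
         M2 = c("s_p", "s_v", "w"),
         M3 = c("s_p", "s_v", "w0", "alpha"),
         M4 = c("s_p", "s_v", "w_p", "w_v"),
         M5 = c("s_p", "s_v", "w0_p", "w0_v", "alpha_p", "alpha_v"))
}

.n_free <- function(model) length(perception_param_names(model))

.param_bounds <- function(name) {
  switch(sub("_[pv]$", "", name),
         s = c(0, 5), w = c(0, 1), w0 = c(0, 1), alpha = c(-1, 1),
         stop("unknown parameter name: ", name))
}

#' Construct a validated perception-parameter set
#'
#' @param model One of `"M1"`..`"M5"`.
#' @param ... Named parameter values; exactly the free parameters of
#'   `model` (see [perception_param_names()]), each within its bounds
#'   (`s` in \[0,5\], `w`/`w0` in \[0,1\], `alpha` in \[-1,1\]).
#' @return Object of class `perception_params`.
#' @export
perception_params <- function(model, ...) {
  model <- match.arg(model, .perception_models)
  par <- unlist(list(...))
  need <- perception_param_names(model)
  if (!setequal(names(par), need))
    stop(sprintf("%s requires exactly the parameters: %s", model,
                 paste(need, collapse = ", ")))
  par <- par[need]
  for (nm in need) {
    bd <- .param_bounds(nm)
    if (!(par[[nm]] >= bd[1L] && par[[nm]] <= bd[2L]))
      stop(sprintf("%s = %g outside its bounds [%g, %g]",
                   nm, par[[nm]], bd[1L], bd[2L]))
  }
  structure(list(model = model, par = par), class = "perception_params")
}

#' @export
print.perception_params <- function(x, ...) {
  cat(sprintf("perception model %s parameters:\n", x$model))
  print(round(x$par, 4))
  invisible(x)
}

#' Aggregate calibration trials into a calibration table
#'
#' Averages stimulus-response task ratings per participant x modality x
#' intensity level. This table supplies the "intensity" term of all
#' perception models. A warning (not an error) is raised when a
#' participant's cell means are not nondecreasing in intensity.
#'
#' @param trials Data frame with `participant`, `modality`,
#'   `intensity_level` and `rating` columns.
#' @return Data frame with columns `participant`, `modality`,
#'   `intensity_level`, `calib_mean`.
#' @export
calibration_table <- function(trials) {
  .require_cols(trials, c("participant", "modality", "intensity_level",
                          "rating"), "calibration trials")
  tab <- stats::aggregate(rating ~ participant + modality + intensity_level,
                          data = trials, FUN = mean)
  names(tab)[names(tab) == "rating"] <- "calib_mean"
  tab <- tab[order(tab$participant, tab$modality, tab$intensity_level), ]
  rownames(tab) <- NULL
  bad <- vapply(split(tab, list(tab$participant, tab$modality), drop = TRUE),
                function(g) is.unsorted(g$calib_mean[order(g$intensity_level)]),
                logical(1L))
  if (any(bad))
    warning("calibration means not nondecreasing in intensity for: ",
            paste(names(bad)[bad], collapse = ", "))
  tab
}

# vectorized calibration lookup; errors on any missing cell
.calib_lookup <- function(calibration, participant, modality, level) {
  idx <- match(paste(participant, modality, level),
               paste(calibration$participant, calibration$modality,
                     calibration$intensity_level))
  if (anyNA(idx)) {
    bad <- unique(paste(participant, modality, level)[is.na(idx)])
    stop("missing calibration cell(s): ", paste(bad, collapse = "; "))
  }
  calibration$calib_mean[idx]
}

#' Attach the calibration ("intensity") term to a trial table
#'
#' @param trials Cued-perception trials with `participant`, `modality`,
#'   `intensity_level`.
#' @param calibration A [calibration_table()].
#' @return `trials` with an added `calib` column.
#' @export
attach_calibration <- function(trials, calibration) {
  .require_cols(trials, c("participant", "modality", "intensity_level"))
  trials$calib <- .calib_lookup(calibration, trials$participant,
                                trials$modality, trials$intensity_level)
  trials
}

# static-model predictions; par is a named vector; w resolved per model
.static_predict <- function(model, par, calib, expv, is_pain) {
  s <- ifelse(is_pain, par[["s_p"]], par[["s_v"]])
  base <- calib * s
  w <- switch(model,
              M1 = 0,
              M2 = par[["w"]],
              M4 = ifelse(is_pain, par[["w_p"]], par[["w_v"]]))
  (1 - w) * base + w * expv
}

# w trajectory of the learning models in fit mode: prediction errors come
# from the observed ratings, so the trajectory depends only on (w0, alpha)
.learning_traj <- function(is_pain, ratings, expv, w0, alpha,
                           w0_v = NULL, alpha_v = NULL, by_modality = FALSE) {
  n <- length(ratings)
  wt <- numeric(n)
  if (!by_modality) {
    w <- w0
    for (t in seq_len(n)) {
      wt[t] <- w
      w <- min(max(w - alpha * (ratings[t] - expv[t]) / 100, 0), 1)
    }
  } else {
    wp <- w0
    wv <- w0_v
    for (t in seq_len(n)) {
      if (is_pain[t]) {
        wt[t] <- wp
        wp <- min(max(wp - alpha * (ratings[t] - expv[t]) / 100, 0), 1)
      } else {
        wt[t] <- wv
        wv <- min(max(wv - alpha_v * (ratings[t] - expv[t]) / 100, 0), 1)
      }
    }
  }
  wt
}

#' Run the prediction-error learning models over an ordered trial sequence
#'
#' Models M3 and M5 update the cue weight trial by trial:
#' `PE(t) = (rating(t) - expectation(t)) / 100` and
#' `w(t+1) = clamp(w(t) - alpha * PE(t), 0, 1)`. In `"fit"` mode `rating(t)`
#' is the observed rating (one-step-ahead prediction); in `"simulate"` mode
#' it is the realized noisy rating generated on the fly, clipped to the
#' 0-100 scale. M5 maintains separate `(w, alpha)` streams per modality.
#'
#' @param trials Ordered trial table with `modality`, `calib`, `expectation`
#'   columns, plus `perception_rating` in fit mode.
#' @param params A [perception_params()] object for M3 or M5.
#' @param mode `"fit"` or `"simulate"`.
#' @param noise_sd Gaussian rating noise SD used in simulate mode.
#' @return List with `predictions`, the `w` trajectory (weight in force on
#'   each trial), and in simulate mode the realized `ratings`.
#' @export
run_learning <- function(trials, params, mode = c("fit", "simulate"),
                         noise_sd = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "perception_params"))
  if (!params$model %in% c("M3", "M5"))
    stop("run_learning applies to the learning models M3 and M5")
  .require_cols(trials, c("modality", "calib", "expectation"))
  par <- params$par
  is_pain <- trials$modality == "pain"
  calib <- trials$calib
  expv <- trials$expectation
  n <- nrow(trials)
  by_mod <- params$model == "M5"
  if (mode == "fit") {
    .require_cols(trials, "perception_rating")
    y <- trials$perception_rating
    if (anyNA(y)) stop("fit mode requires an observed rating on every trial")
    wt <- if (by_mod)
      .learning_traj(is_pain, y, expv, par[["w0_p"]], par[["alpha_p"]],
                     par[["w0_v"]], par[["alpha_v"]], by_modality = TRUE)
    else
      .learning_traj(is_pain, y, expv, par[["w0"]], par[["alpha"]])
    s <- ifelse(is_pain, par[["s_p"]], par[["s_v"]])
    pred <- (1 - wt) * (calib * s) + wt * expv
    return(list(predictions = pred, w = wt))
  }
  # simulate mode: realized ratings feed the updates
  noise <- stats::rnorm(n, 0, noise_sd)
  s <- ifelse(is_pain, par[["s_p"]], par[["s_v"]])
  pred <- numeric(n)
  rating <- numeric(n)
  wt <- numeric(n)
  if (!by_mod) {
    w <- par[["w0"]]
    alpha <- par[["alpha"]]
    for (t in seq_len(n)) {
      wt[t] <- w
      pred[t] <- (1 - w) * (calib[t] * s[t]) + w * expv[t]
      rating[t] <- min(max(pred[t] + noise[t], 0), 100)
      w <- min(max(w - alpha * (rating[t] - expv[t]) / 100, 0), 1)
    }
  } else {
    wp <- par[["w0_p"]]
    wv <- par[["w0_v"]]
    for (t in seq_len(n)) {
      if (is_pain[t]) {
        wt[t] <- wp
        pred[t] <- (1 - wp) * (calib[t] * s[t]) + wp * expv[t]
        rating[t] <- min(max(pred[t] + noise[t], 0), 100)
        wp <- min(max(wp - par[["alpha_p"]] * (rating[t] - expv[t]) / 100,
                      0), 1)
      } else {
        wt[t] <- wv
        pred[t] <- (1 - wv) * (calib[t] * s[t]) + wv * expv[t]
        rating[t] <- min(max(pred[t] + noise[t], 0), 100)
        wv <- min(max(wv - par[["alpha_v"]] * (rating[t] - expv[t]) / 100,
                      0), 1)
      }
    }
  }
  list(predictions = pred, w = wt, ratings = rating)
}

#' Per-trial predictions of a perception model
#'
#' @param trials Trial table with `modality`, `intensity_level` and (for
#'   M2-M5) an `expectation` column holding each trial's cue-based
#'   expectation; either a `calib` column or `calibration` must be supplied.
#' @param params A [perception_params()] object.
#' @param calibration Optional [calibration_table()] used to attach the
#'   intensity term when `trials$calib` is absent.
#' @return Numeric vector of predicted VAS ratings. Model predictions are
#'   never clipped; only simulated observed ratings are.
#' @export
predict_perception <- function(trials, params, calibration = NULL) {
  stopifnot(inherits(params, "perception_params"))
  if (is.null(trials$calib)) {
    if (is.null(calibration))
      stop("supply a calibration table or a precomputed calib column")
    trials <- attach_calibration(trials, calibration)
  }
  model <- params$model
  if (model %in% c("M3", "M5"))
    return(run_learning(trials, params, mode = "fit")$predictions)
  if (model != "M1") .require_cols(trials, "expectation")
  expv <- if (model == "M1") 0 else trials$expectation
  .static_predict(model, params$par, trials$calib, expv,
                  trials$modality == "pain")
}

.default_perception_starts <- function(model) {
  switch(model,
    M1 = expand.grid(s_p = c(0.5, 1.5), s_v = c(0.5, 1.5)),
    M2 = expand.grid(s_p = c(0.5, 1.5), s_v = c(0.5, 1.5), w = c(0.2, 0.8)),
    M3 = expand.grid(s_p = c(0.5, 1.5), s_v = c(0.5, 1.5), w0 = c(0.2, 0.8),
                     alpha = c(-0.25, 0.25)),
    M4 = expand.grid(s_p = c(0.5, 1.5), s_v = c(0.5, 1.5),
                     w_p = c(0.2, 0.8), w_v = c(0.2, 0.8)),
    M5 = expand.grid(s_p = 1, s_v = 1, w0_p = c(0.2, 0.8),
                     w0_v = c(0.2, 0.8), alpha_p = c(-0.25, 0.25),
                     alpha_v = c(-0.25, 0.25)))
}

#' Fit one perception model to a participant's cued-perception trials
#'
#' Bounded least squares (L-BFGS-B) over the model's free parameters with a
#' multi-start grid. The model AIC is computed under the Gaussian
#' ordinary-least-squares likelihood as `n * log(RSS / n) + 2p`, with the
#' RSS floored at a per-trial mean square of 1e-6 (an RMSE of 0.001 VAS
#' units, far below measurement resolution) so the AIC stays finite on
#' noiseless data and numerically exact fits are ordered by the parameter
#' penalty alone.
#'
#' @param trials Ordered trials of one participant with
#'   `perception_rating`, `modality`, `intensity_level`, `expectation`
#'   (M2-M5) and either a `calib` column or `calibration`.
#' @param model One of `"M1"`..`"M5"`.
#' @param calibration Optional [calibration_table()].
#' @param init_grid Optional data frame of start values (columns =
#'   parameter names); defaults to a small factorial grid.
#' @param tol Convergence tolerance on the residual sum of squares.
#' @return Object of class `perception_fit`: `model`, `params` (named
#'   vector), `rss`, `n`, `aic`, `predictions`, `w_trajectory` (learning
#'   models), `converged`, `multistart_log`.
#' @export
fit_perception <- function(trials, model, calibration = NULL,
                           init_grid = NULL, tol = 1e-10) {
  model <- match.arg(model, .perception_models)
  .require_cols(trials, c("modality", "intensity_level", "perception_rating"))
  if (is.null(trials$calib)) {
    if (is.null(calibration))
      stop("supply a calibration table or a precomputed calib column")
    trials <- attach_calibration(trials, calibration)
  }
  if (model != "M1") .require_cols(trials, "expectation")
  keep <- is.finite(trials$perception_rating)
  trials <- trials[keep, , drop = FALSE]
  nm <- perception_param_names(model)
  p <- length(nm)
  n <- nrow(trials)
  if (n < p + 2L)
    stop(sprintf("%s needs at least %d trials (free parameters + 2)",
                 model, p + 2L))
  y <- trials$perception_rating
  is_pain <- trials$modality == "pain"
  calib <- trials$calib
  expv <- if (model == "M1") rep(0, n) else trials$expectation
  obj <- switch(model,
    M1 = function(par) {
      names(par) <- nm
      sum((.static_predict("M1", par, calib, expv, is_pain) - y)^2)
    },
    M2 = function(par) {
      names(par) <- nm
      sum((.static_predict("M2", par, calib, expv, is_pain) - y)^2)
    },
    M4 = function(par) {
      names(par) <- nm
      sum((.static_predict("M4", par, calib, expv, is_pain) - y)^2)
    },
    M3 = function(par) {
      wt <- .learning_traj(is_pain, y, expv, par[3L], par[4L])
      s <- ifelse(is_pain, par[1L], par[2L])
      sum(((1 - wt) * (calib * s) + wt * expv - y)^2)
    },
    M5 = function(par) {
      wt <- .learning_traj(is_pain, y, expv, par[3L], par[5L],
                           par[4L], par[6L], by_modality = TRUE)
      s <- ifelse(is_pain, par[1L], par[2L])
      sum(((1 - wt) * (calib * s) + wt * expv - y)^2)
    })
  starts <- if (is.null(init_grid)) .default_perception_starts(model)
            else init_grid[, nm, drop = FALSE]
  bd <- vapply(nm, .param_bounds, numeric(2L))
  ctl <- list(factr = max(tol / .Machine$double.eps, 1))
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                   lower = bd[1L, ], upper = bd[2L, ], control = ctl),
      error = function(e) e)
  }
  ok <- !vapply(runs, inherits, logical(1L), "error")
  if (!any(ok)) {
    msgs <- unique(vapply(runs, conditionMessage, character(1L)))
    stop("all optimizer starts failed: ", paste(msgs, collapse = "; "))
  }
  vals <- vapply(seq_along(runs), function(i)
    if (ok[i]) runs[[i]]$value else Inf, 0)
  best <- runs[[which.min(vals)]]
  par <- stats::setNames(best$par, nm)
  # rebuild predictions and trajectory at the optimum
  if (model %in% c("M3", "M5")) {
    wt <- if (model == "M3")
      .learning_traj(is_pain, y, expv, par[["w0"]], par[["alpha"]])
    else
      .learning_traj(is_pain, y, expv, par[["w0_p"]], par[["alpha_p"]],
                     par[["w0_v"]], par[["alpha_v"]], by_modality = TRUE)
    s <- ifelse(is_pain, par[["s_p"]], par[["s_v"]])
    pred <- (1 - wt) * (calib * s) + wt * expv
  } else {
    wt <- NULL
    pred <- .static_predict(model, par, calib, expv, is_pain)
  }
  rss <- best$value
  structure(list(
    model = model, params = par, rss = rss, n = n,
    aic = n * log(max(rss, n * 1e-6) / n) + 2 * p,
    predictions = pred, observed = y, w_trajectory = wt,
    converged = best$convergence == 0L,
    multistart_log = data.frame(rss = vals,
                                convergence = vapply(seq_along(runs),
                                  function(i) if (ok[i])
                                    runs[[i]]$convergence else NA_integer_,
                                  0L)),
    participant = if (!is.null(trials$participant))
      trials$participant[1L] else NA,
    call = match.call()),
    class = "perception_fit")
}

#' @export
print.perception_fit <- function(x, ...) {
  cat(sprintf("Cued-perception observer model %s (%d free parameters)\n",
              x$model, length(x$params)))
  print(round(x$params, 4))
  cat(sprintf("  n = %d trials, RSS = %.3f, AIC = %.2f\n",
              x$n, x$rss, x$aic))
  invisible(x)
}

#' @export
coef.perception_fit <- function(object, ...) object$params

#' @export
fitted.perception_fit <- function(object, ...) object$predictions

#' @export
residuals.perception_fit <- function(object, ...)
  object$observed - object$predictions

#' Plot a perception fit: observed vs predicted, and the weight trajectory
#' for learning models
#'
#' @param x A `perception_fit`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.perception_fit <- function(x, ...) {
  if (!is.null(x$w_trajectory)) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(x$predictions, x$observed,
                 xlab = "predicted rating (VAS)",
                 ylab = "observed rating (VAS)",
                 main = sprintf("%s (AIC %.1f)", x$model, x$aic), ...)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(x$w_trajectory)) {
    graphics::plot(x$w_trajectory, type = "s", ylim = c(0, 1),
                   xlab = "trial", ylab = "cue weight w(t)",
                   main = "learned weight trajectory")
  }
  invisible(x)
}

#' Akaike information criterion of a perception fit
#'
#' Computed under the Gaussian OLS likelihood as `n * log(RSS / n) + 2p`.
#'
#' @param object A `perception_fit`.
#' @param ... Unused.
#' @param k Unused (the penalty is fixed at 2 per parameter).
#' @export
AIC.perception_fit <- function(object, ..., k = 2) object$aic

#' Fit a set of perception models to every participant
#'
#' Attaches the calibration term and the cue-based expectation (from each
#' participant's fitted expectation-model parameters) to the trials, then
#' fits the requested models per participant.
#'
#' @param trials Cued-perception trial table (`participant`, `modality`,
#'   `intensity_level`, `perception_rating`, cue columns, in presentation
#'   order within participant).
#' @param calibration A [calibration_table()].
#' @param expectation_fits Data frame from [fit_expectation_cohort()]
#'   giving each participant x modality `(k, b)`; ignored when `trials`
#'   already carries an `expectation` column.
#' @param models Character vector of models to fit (default all five).
#' @param ... Passed to [fit_perception()].
#' @return Named list (one element per model) of lists of `perception_fit`
#'   objects in participant order, with a `participants` attribute.
#' @export
fit_perception_cohort <- function(trials, calibration,
                                  expectation_fits = NULL,
                                  models = .perception_models, ...) {
  .require_cols(trials, c("participant", "modality", "intensity_level",
                          "perception_rating"))
  models <- match.arg(models, .perception_models, several.ok = TRUE)
  trials <- attach_calibration(trials, calibration)
  if (is.null(trials$expectation)) {
    if (is.null(expectation_fits))
      stop("supply expectation_fits or a precomputed expectation column")
    trials$expectation <- expectation_from_fits(trials, expectation_fits)
  }
  ids <- unique(trials$participant)
  fits <- lapply(models, function(m)
    lapply(ids, function(id)
      fit_perception(trials[trials$participant == id, , drop = FALSE],
                     model = m, ...)))
  names(fits) <- models
  attr(fits, "participants") <- ids
  fits
}

#' Cue-based expectations from fitted expectation-model parameters
#'
#' @param trials Trial table with `participant`, `modality` and cue columns.
#' @param expectation_fits Data frame with `participant`, `modality`, `k`,
#'   `b`.
#' @return Numeric vector of per-trial expectations.
#' @export
expectation_from_fits <- function(trials, expectation_fits) {
  .require_cols(expectation_fits, c("participant", "modality", "k", "b"),
                "expectation fits")
  v <- .cue_matrix(trials)
  out <- rep(NA_real_, nrow(trials))
  key <- paste(trials$participant, trials$modality)
  fkey <- paste(expectation_fits$participant, expectation_fits$modality)
  for (kk in unique(key)) {
    j <- match(kk, fkey)
    if (is.na(j)) stop("no fitted expectation parameters for ", kk)
    sel <- key == kk
    out[sel] <- .predict_expectation_mat(v[sel, , drop = FALSE],
                                         expectation_fits$k[j],
                                         expectation_fits$b[j])
  }
  out
}
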