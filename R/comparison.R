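# Nested F-test and AIC comparison of the five observer models.
#
# Declared nesting lattice: M1 < M2 < M3, M2 < M4 < M5, M3 < M5 (and its
# transitive closure). M3 and M4 both have four parameters and are not
# nested in each other.

.nested_pairs <- matrix(c(
  "M1", "M2",
  "M2", "M3",
  "M1", "M3",
  "M2", "M4",
  "M1", "M4",
  "M4", "M5",
  "M2", "M5",
  "M1", "M5",
  "M3", "M5"), ncol = 2L, byrow = TRUE,
  dimnames = list(NULL, c("simple", "complex")))

.is_nested <- function(simple, complex) {
  any(.nested_pairs[, "simple"] == simple &
      .nested_pairs[, "complex"] == complex)
}

.f_test <- function(rss_s, rss_c, p_s, p_c, n) {
  df1 <- p_c - p_s
  df2 <- n - p_c
  num <- max(rss_s - rss_c, 0) / df1
  f <- if (num == 0) 0 else num / (max(rss_c, 1e-12) / df2)
  list(F = f, df1 = df1, df2 = df2,
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Nested F test between two perception-model fits
#'
#' `F = ((RSS_s - RSS_c) / (p_c - p_s)) / (RSS_c / (n - p_c))`, with a
#' negative numerator floored at zero (so `RSS_s == RSS_c` gives `F = 0`,
#' `p = 1`). Only pairs on the declared nesting lattice are accepted.
#'
#' @param fit_simple,fit_complex `perception_fit` objects for the same
#'   trials (simpler model first).
#' @param n Number of trials; defaults to the complex fit's `n`.
#' @return List with `models`, `F`, `df1`, `df2`, `p.value`.
#' @export
compare_nested <- function(fit_simple, fit_complex, n = fit_complex$n) {
  stopifnot(inherits(fit_simple, "perception_fit"),
            inherits(fit_complex, "perception_fit"))
  ms <- fit_simple$model
  mc <- fit_complex$model
  if (!.is_nested(ms, mc))
    stop(sprintf("%s is not nested in %s on the declared lattice", ms, mc))
  if (fit_simple$n != fit_complex$n)
    stop("fits compare different numbers of trials")
  ft <- .f_test(fit_simple$rss, fit_complex$rss,
                .n_free(ms), .n_free(mc), n)
  c(list(models = c(simple = ms, complex = mc)), ft)
}

#' Group-level comparison of the five observer models
#'
#' Collects participant-level nested F tests for every pair on the nesting
#' lattice, a group F test computed from the mean residual sum of squares
#' across participants (with `n` taken as the mean trial count per
#' participant -- a reporting convention; the participant-level tests carry
#' the inferential weight), and AIC per model (summed across participants,
#' and a group AIC from the mean RSS). The AIC winner is the model with the
#' lowest participant-summed AIC.
#'
#' @param fits Output of [fit_perception_cohort()] (named list of
#'   per-participant fit lists; all models fitted on identical trials).
#' @param alpha Significance level used for the stepwise group-F winner.
#' @return Object of class `perception_comparison` with elements
#'   `participant_tests` (long data frame of per-participant F tests),
#'   `group_tests`, `aic` (per-model summaries), `mean_rss`,
#'   `winner_aic`, `winner_group_f`, `confusion` slot left `NULL`.
#' @export
compare_perception_models <- function(fits, alpha = 0.05) {
  models <- names(fits)
  n_part <- unique(vapply(fits, length, 0L))
  if (length(n_part) != 1L)
    stop("participant sets differ across models")
  ids <- attr(fits, "participants")
  if (is.null(ids)) ids <- seq_len(n_part)
  n_by_part <- vapply(fits[[1L]], function(f) as.numeric(f$n), 0)
  for (m in models) {
    nm <- vapply(fits[[m]], function(f) as.numeric(f$n), 0)
    if (!identical(nm, n_by_part))
      stop("models were fitted on differing trial sets")
  }
  pairs <- .nested_pairs[.nested_pairs[, 1L] %in% models &
                         .nested_pairs[, 2L] %in% models, , drop = FALSE]
  part_rows <- list()
  group_rows <- list()
  mean_rss <- vapply(models, function(m)
    mean(vapply(fits[[m]], function(f) f$rss, 0)), 0)
  n_eff <- mean(n_by_part)
  for (r in seq_len(nrow(pairs))) {
    ms <- pairs[r, 1L]
    mc <- pairs[r, 2L]
    for (i in seq_len(n_part)) {
      ft <- .f_test(fits[[ms]][[i]]$rss, fits[[mc]][[i]]$rss,
                    .n_free(ms), .n_free(mc), n_by_part[i])
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        participant = ids[i], simple = ms, complex = mc, F = ft$F,
        df1 = ft$df1, df2 = ft$df2, p.value = ft$p.value,
        stringsAsFactors = FALSE)
    }
    gt <- .f_test(mean_rss[[ms]], mean_rss[[mc]],
                  .n_free(ms), .n_free(mc), n_eff)
    group_rows[[length(group_rows) + 1L]] <- data.frame(
      simple = ms, complex = mc, F = gt$F, df1 = gt$df1, df2 = gt$df2,
      p.value = gt$p.value, stringsAsFactors = FALSE)
  }
  part_df <- do.call(rbind, part_rows)
  group_df <- do.call(rbind, group_rows)
  aic_df <- data.frame(
    model = models,
    n_free = vapply(models, .n_free, 0L),
    aic_sum = vapply(models, function(m)
      sum(vapply(fits[[m]], function(f) f$aic, 0)), 0),
    aic_group = vapply(models, function(m)
      n_eff * log(max(mean_rss[[m]], n_eff * 1e-6) / n_eff) +
        2 * .n_free(m), 0),
    mean_rss = unname(mean_rss), stringsAsFactors = FALSE)
  rownames(aic_df) <- NULL
  winner_aic <- aic_df$model[which.min(aic_df$aic_sum)]
  structure(list(models = models,
                 participant_tests = part_df,
                 group_tests = group_df,
                 aic = aic_df,
                 mean_rss = mean_rss,
                 n_eff = n_eff,
                 winner_aic = winner_aic,
                 winner_group_f = .stepwise_winner(group_df, models, alpha)),
            class = "perception_comparison")
}

# stepwise walk up the nesting lattice using the group F tests: move to a
# more complex model only when it significantly improves on the current one
.stepwise_winner <- function(group_df, models, alpha) {
  current <- "M1"
  if (!current %in% models) return(models[1L])
  repeat {
    direct <- switch(current,
                     M1 = "M2", M2 = c("M3", "M4"), M3 = "M5", M4 = "M5",
                     M5 = character())
    direct <- intersect(direct, models)
    if (!length(direct)) break
    cand <- group_df[group_df$simple == current &
                     group_df$complex %in% direct &
                     group_df$p.value < alpha, , drop = FALSE]
    if (!nrow(cand)) break
    current <- cand$complex[which.max(cand$F)]
  }
  current
}

#' @export
print.perception_comparison <- function(x, ...) {
  cat("Nested comparison of cued-perception observer models\n")
  cat(sprintf("  participants: %d, mean trials: %.1f\n",
              length(unique(x$participant_tests$participant)), x$n_eff))
  cat("\nAIC (participant-summed) and mean RSS per model:\n")
  print(x$aic, row.names = FALSE, digits = 6)
  cat("\nGroup F tests (mean RSS across participants):\n")
  print(x$group_tests, row.names = FALSE, digits = 4)
  rej <- stats::aggregate(p.value ~ simple + complex,
                          data = x$participant_tests,
                          FUN = function(p) mean(p < 0.05))
  names(rej)[3L] <- "prop_significant"
  cat("\nShare of participants with a significant improvement (alpha = 0.05):\n")
  print(rej, row.names = FALSE, digits = 3)
  cat(sprintf("\nWinner by summed AIC: %s; by stepwise group F: %s\n",
              x$winner_aic, x$winner_group_f))
  invisible(x)
}
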