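# Group-level nonparametric tests on fitted expectation-model parameters.

# two-sided Wilcoxon signed-rank of x against mu; zeros are dropped (the
# exact-conditional convention); the fully degenerate case (all values equal
# mu) is reported with p = 1
.signed_rank <- function(x, mu) {
  x <- x[is.finite(x)]
  med <- stats::median(x)
  if (all(x == mu))
    return(list(median = med, statistic = NA_real_, p.value = 1,
                n = length(x), degenerate = TRUE))
  ht <- suppressWarnings(stats::wilcox.test(x, mu = mu,
                                            alternative = "two.sided"))
  list(median = med, statistic = unname(ht$statistic),
       p.value = ht$p.value, n = length(x), degenerate = FALSE)
}

#' Group-level tests of the expectation-model parameters
#'
#' For each modality, runs two-sided Wilcoxon signed-rank tests of the
#' fitted `k` values against 1 (equal inlier/outlier weighting) and of the
#' fitted `b` values against 0 (equal below/above-mean weighting), and
#' Spearman rank correlations of `k` and `b` between modalities across
#' participants.
#'
#' @param fits Data frame from [fit_expectation_cohort()] (columns
#'   `participant`, `modality`, `k`, `b`).
#' @return An object of class `expectation_group_tests`: per-modality test
#'   lists (`median`, `statistic`, `p.value`) for `k` and `b`, and the
#'   cross-modality Spearman results.
#' @export
expectation_group_tests <- function(fits) {
  .require_cols(fits, c("participant", "modality", "k", "b"), "fits table")
  mods <- intersect(.modalities, unique(fits$modality))
  tests <- lapply(mods, function(m) {
    sel <- fits$modality == m
    if (sum(sel) < 6L)
      stop("need at least 6 participants per modality for group tests")
    list(k = .signed_rank(fits$k[sel], 1),
         b = .signed_rank(fits$b[sel], 0))
  })
  names(tests) <- mods
  spearman <- NULL
  if (length(mods) == 2L) {
    wide <- merge(fits[fits$modality == mods[1L], c("participant", "k", "b")],
                  fits[fits$modality == mods[2L], c("participant", "k", "b")],
                  by = "participant", suffixes = paste0("_", mods))
    if (nrow(wide) >= 3L) {
      sp <- function(a, b) {
        ct <- suppressWarnings(
          stats::cor.test(a, b, method = "spearman", exact = FALSE))
        list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(a))
      }
      spearman <- list(
        k = sp(wide[[paste0("k_", mods[1L])]], wide[[paste0("k_", mods[2L])]]),
        b = sp(wide[[paste0("b_", mods[1L])]], wide[[paste0("b_", mods[2L])]]))
    }
  }
  structure(list(modalities = mods, tests = tests, spearman = spearman),
            class = "expectation_group_tests")
}

#' @export
print.expectation_group_tests <- function(x, ...) {
  cat("Group tests of cue-weighting parameters\n")
  for (m in x$modalities) {
    tk <- x$tests[[m]]$k
    tb <- x$tests[[m]]$b
    cat(sprintf("  %s: median k = %.3f (vs 1: V = %s, p = %.4g)\n", m,
                tk$median, format(tk$statistic), tk$p.value))
    cat(sprintf("  %s: median b = %.3f (vs 0: V = %s, p = %.4g)\n", m,
                tb$median, format(tb$statistic), tb$p.value))
  }
  if (!is.null(x$spearman)) {
    cat(sprintf("  cross-modality Spearman: k rho = %.3f (p = %.4g), b rho = %.3f (p = %.4g)\n",
                x$spearman$k$rho, x$spearman$k$p.value,
                x$spearman$b$rho, x$spearman$b$p.value))
  }
  invisible(x)
}
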