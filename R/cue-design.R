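#' Enumerate the factorial trial design of one task
#'
#' Builds the complete, randomized trial list for one of the three tasks of
#' the paradigm:
#' \describe{
#'   \item{`stimulus_response`}{2 single-modality blocks of 25 trials
#'     (5 intensity levels x 5 repetitions each); 50 trials total. Used to
#'     calibrate each participant's stimulus-response function.}
#'   \item{`expectation`}{6 blocks of 60 trials. Within each modality the
#'     cells are 5 cue means \{30, 40, 50, 60, 70\} x 2 cue SDs \{5, 12.5\} x
#'     3 skew levels = 30 cells, each repeated 6 times (twice per
#'     same-modality block); 60 unique cells and 360 trials overall. The
#'     first three blocks are one modality and the last three the other.}
#'   \item{`cued_perception`}{6 blocks of 24 trials, each split into two
#'     single-modality mini-blocks of 12. Cells are 2 stimulus intensities x
#'     2 cue means \{30, 70\} x 2 cue SDs x 3 skew levels per modality
#'     (48 unique cells), each presented 3 times; 144 trials total. The two
#'     stimulus intensity levels index levels 2 and 4 of the
#'     stimulus-response task so that calibration lookups are direct.}
#' }
#' Trial order within blocks (and modality/mini-block order) is randomized
#' under `seed`.
#'
#' @param task One of `"stimulus_response"`, `"expectation"`,
#'   `"cued_perception"`.
#' @param seed Optional integer seed; the global RNG state is restored on
#'   exit.
#' @return A data frame with columns `task`, `block`, `mini_block`, `trial`,
#'   `modality`, `intensity_level`, `cue_mean_level`, `cue_sd_level`,
#'   `cue_skew_level`. Columns that do not apply to a task are `NA`.
#' @examples
#' d <- enumerate_design("expectation", seed = 1)
#' nrow(d)  # 360
#' @export
enumerate_design <- function(task, seed = NULL) {
  if (!(is.character(task) && length(task) == 1L && task %in% .tasks))
    stop("unknown task; valid tasks are: ", paste(.tasks, collapse = ", "))
  .with_seed(seed, {
    des <- switch(task,
      stimulus_response = .design_sr(),
      expectation = .design_expect(),
      cued_perception = .design_cp())
    des$task <- task
    rownames(des) <- NULL
    des[, c("task", "block", "mini_block", "trial", "modality",
            "intensity_level", "cue_mean_level", "cue_sd_level",
            "cue_skew_level")]
  })
}

.design_sr <- function() {
  mods <- sample(.modalities)
  blocks <- lapply(1:2, function(b) {
    cells <- data.frame(modality = mods[b],
                        intensity_level = rep(1:5, each = 5),
                        stringsAsFactors = FALSE)
    cells <- cells[sample(nrow(cells)), , drop = FALSE]
    data.frame(block = b, mini_block = NA_integer_,
               trial = seq_len(nrow(cells)), cells,
               cue_mean_level = NA_real_, cue_sd_level = NA_real_,
               cue_skew_level = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}

.design_expect <- function() {
  mods <- sample(.modalities)
  cells <- expand.grid(cue_mean_level = .exp_means, cue_sd_level = .cue_sds,
                       cue_skew_level = .skew_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blocks <- lapply(1:6, function(b) {
    m <- if (b <= 3) mods[1] else mods[2]
    bl <- rbind(cells, cells)  # each modality cell twice per block, 6 reps overall
    bl <- bl[sample(nrow(bl)), , drop = FALSE]
    data.frame(block = b, mini_block = NA_integer_,
               trial = seq_len(nrow(bl)), modality = m,
               intensity_level = NA_real_, bl, stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}

.design_cp <- function() {
  per_mod <- lapply(.modalities, function(m) {
    cells <- expand.grid(intensity_level = c(2, 4),
                         cue_mean_level = .cp_means, cue_sd_level = .cue_sds,
                         cue_skew_level = .skew_levels,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    reps <- cells[rep(seq_len(nrow(cells)), 3L), , drop = FALSE]
    reps <- reps[sample(nrow(reps)), , drop = FALSE]
    reps$mini_of_mod <- rep(1:6, each = 12L)
    reps$modality <- m
    reps
  })
  names(per_mod) <- .modalities
  blocks <- lapply(1:6, function(b) {
    order_mods <- sample(.modalities)
    half <- lapply(1:2, function(j) {
      m <- order_mods[j]
      rows <- per_mod[[m]][per_mod[[m]]$mini_of_mod == b, , drop = FALSE]
      data.frame(block = b, mini_block = j, modality = m,
                 intensity_level = rows$intensity_level,
                 cue_mean_level = rows$cue_mean_level,
                 cue_sd_level = rows$cue_sd_level,
                 cue_skew_level = rows$cue_skew_level,
                 stringsAsFactors = FALSE)
    })
    bl <- do.call(rbind, half)
    bl$trial <- seq_len(nrow(bl))
    bl
  })
  do.call(rbind, blocks)
}

#' Adjusted Fisher-Pearson standardized sample skewness (G1)
#'
#' `G1 = sqrt(n(n-1))/(n-2) * m3 / m2^(3/2)` with `m2`, `m3` the biased
#' central sample moments. This is the estimator used to enforce the skew
#' category bounds of the cue generator (symmetric: |G1| <= 0.035;
#' negative: G1 < -0.3; positive: G1 > 0.3).
#'
#' @param values Numeric vector, length >= 3, with nonzero variance.
#' @return The G1 skewness (dimensionless scalar).
#' @export
sample_skewness <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values to estimate skewness")
  d <- values - mean(values)
  m2 <- mean(d^2)
  if (m2 <= 0) stop("skewness is undefined for zero-variance input")
  sqrt(n * (n - 1)) / (n - 2) * mean(d^3) / m2^1.5
}

# row-wise G1 for an n x p matrix of cue values
.row_skewness <- function(m) {
  p <- ncol(m)
  d <- m - rowMeans(m)
  m2 <- rowMeans(d^2)
  m3 <- rowMeans(d^3)
  sqrt(p * (p - 1)) / (p - 2) * m3 / m2^1.5
}

#' Specify one cue distribution's design cell
#'
#' @param modality `"pain"` or `"vision"`.
#' @param mean_target Target cue mean on the VAS; must belong to the task's
#'   allowed set (expectation: 30/40/50/60/70; cued perception: 30/70).
#' @param sd_target Target cue SD; 5 or 12.5 VAS units.
#' @param skew_level `"negative"`, `"symmetric"` or `"positive"`.
#' @param task Task whose allowed mean set applies (default
#'   `"expectation"`).
#' @return An object of class `cue_spec`.
#' @export
cue_spec <- function(modality, mean_target, sd_target, skew_level,
                     task = "expectation") {
  if (!modality %in% .modalities)
    stop("modality must be one of: ", paste(.modalities, collapse = ", "))
  allowed <- if (identical(task, "cued_perception")) .cp_means else .exp_means
  if (!mean_target %in% allowed)
    stop("mean_target must be one of: ", paste(allowed, collapse = ", "))
  # the canonical cells use SD 5 or 12.5; other positive values are allowed
  # for sensitivity work and degenerate-input checks
  if (!is.numeric(sd_target) || length(sd_target) != 1L || sd_target <= 0)
    stop("sd_target must be a positive number (canonical levels: ",
         paste(.cue_sds, collapse = ", "), ")")
  if (!skew_level %in% .skew_levels)
    stop("skew_level must be one of: ", paste(.skew_levels, collapse = ", "))
  structure(list(modality = modality, mean_target = mean_target,
                 sd_target = sd_target, skew_level = skew_level, task = task),
            class = "cue_spec")
}

# Constrained batch generation of n 10-value cue distributions for one cell.
#
# Symmetric cells: 10 normal draws affinely standardized so the realized
# sample mean/SD equal the targets exactly; sets are redrawn until the
# realized G1 skewness is within [-0.035, 0.035] and all values lie in
# [0, 100].
#
# Skewed cells: a standardized distance d ~ U(2.0, 2.5) is drawn for the
# injected extreme element; nine log-normal shape draws (mirrored for
# negative skew) are standardized to the 9-sample mean/SD that make the
# final 10-value statistics hit the targets exactly, and the 10th element is
# placed so that |extreme - mean| / SD = d under the realized 10-value
# mean/SD. Sets are redrawn until the skew-category bound (|G1| > 0.3 on the
# appropriate side) and the [0, 100] range hold.
#
# Returns list(values = n x 10 matrix (extreme element in column 10 for
# skewed cells), skew = realized G1, extreme_d = realized standardized
# distance of the injected element (NA for symmetric)).
.generate_cue_batch <- function(n, mean_target, sd_target, skew_level,
                                max_attempts = 10000) {
  if (!is.finite(sd_target) || sd_target <= 0)
    stop("sd_target must be a positive number")
  if (max_attempts < 1) stop("max_attempts must be >= 1")
  values <- matrix(NA_real_, n, 10L)
  skew <- rep(NA_real_, n)
  exd <- rep(NA_real_, n)
  filled <- 0L
  budget <- as.numeric(max_attempts) * n
  used <- 0
  fail <- c(bounds = 0, skew = 0)
  over <- if (identical(skew_level, "symmetric")) 35L else 4L
  while (filled < n) {
    if (used >= budget) {
      worst <- names(fail)[which.max(fail)]
      stop(sprintf(paste0("cue generation for cell (mean=%g, sd=%g, %s) ",
                          "failed within max_attempts; dominant failing ",
                          "constraint: %s (bounds: %d, skew: %d rejections)"),
                   mean_target, sd_target, skew_level, worst,
                   fail["bounds"], fail["skew"]))
    }
    m <- min(max((n - filled) * over, 200L), 50000L, ceiling(budget - used))
    used <- used + m
    cand <- if (identical(skew_level, "symmetric"))
      .cand_symmetric(m, mean_target, sd_target)
    else
      .cand_skewed(m, mean_target, sd_target,
                   positive = identical(skew_level, "positive"))
    fail["bounds"] <- fail["bounds"] + sum(!cand$ok_bounds)
    fail["skew"] <- fail["skew"] + sum(cand$ok_bounds & !cand$ok_skew)
    ok <- which(cand$ok_bounds & cand$ok_skew)
    if (!length(ok)) next
    take <- ok[seq_len(min(length(ok), n - filled))]
    idx <- filled + seq_along(take)
    values[idx, ] <- cand$values[take, , drop = FALSE]
    skew[idx] <- cand$skew[take]
    exd[idx] <- cand$extreme_d[take]
    filled <- filled + length(take)
  }
  list(values = values, skew = skew, extreme_d = exd)
}

.cand_symmetric <- function(m, M, S) {
  z <- matrix(stats::rnorm(m * 10L), m, 10L)
  mu <- rowMeans(z)
  s <- sqrt(rowSums((z - mu)^2) / 9)
  v <- (z - mu) / s * S + M
  g <- .row_skewness(v)
  okb <- is.finite(g) & rowSums(v < 0 | v > 100) == 0L
  list(values = v, skew = g, extreme_d = rep(NA_real_, m),
       ok_bounds = okb, ok_skew = abs(g) <= 0.035)
}

.cand_skewed <- function(m, M, S, positive) {
  d <- stats::runif(m, 2.0, 2.5)
  # choose c so that the extreme sits exactly d realized (10-value) SDs from
  # the realized mean: d = 2.7 c / sqrt(8 + 0.9 c^2)
  c2 <- 8 * d^2 / (7.29 - 0.9 * d^2)
  cc <- sqrt(c2)
  sgn <- if (positive) 1 else -1
  s9 <- 3 * S / sqrt(8 + 0.9 * c2)     # 9-sample SD giving final SD == S
  m9 <- M - sgn * cc * s9 / 10         # 9-sample mean giving final mean == M
  sdlog <- sqrt(log1p((S / M)^2))      # log-normal shape moment-matched to the cell
  z <- matrix(stats::rlnorm(m * 9L, 0, sdlog), m, 9L) * sgn
  mu <- rowMeans(z)
  sz <- sqrt(rowSums((z - mu)^2) / 8)
  z9 <- (z - mu) / sz * s9 + m9
  y <- m9 + sgn * cc * s9
  v <- cbind(z9, y, deparse.level = 0)
  g <- .row_skewness(v)
  okb <- is.finite(g) & rowSums(v < 0 | v > 100) == 0L
  oks <- if (positive) g > 0.3 else g < -0.3
  list(values = v, skew = g, extreme_d = d, ok_bounds = okb, ok_skew = oks)
}

#' Generate one constrained cue distribution
#'
#' Draws a ten-value cue distribution matching the design cell in `spec`.
#' Symmetric cues are normal draws standardized so the realized mean and SD
#' equal the targets exactly; skewed cues combine nine (mirrored)
#' log-normal shape draws with an injected extreme element placed 2.0-2.5
#' realized SDs from the realized mean on the skew side. Whole sets are
#' redrawn until the realized G1 skewness falls in its category band and all
#' values lie in \[0, 100\].
#'
#' @param spec A [cue_spec()] object.
#' @param seed Optional integer seed (RNG state restored on exit).
#' @param max_attempts Maximum candidate sets drawn before erroring.
#' @return An object of class `cue`: a list with `values` (length 10;
#'   for skewed cues the injected extreme element is `values[10]`), `spec`,
#'   `realized_mean`, `realized_sd`, `realized_skew`, `extreme_index` and
#'   `extreme_d` (standardized distance of the extreme element; `NA` for
#'   symmetric cues).
#' @examples
#' cue <- generate_cue(cue_spec("pain", 50, 5, "symmetric"), seed = 1)
#' mean(cue$values); sd(cue$values)
#' @export
generate_cue <- function(spec, seed = NULL, max_attempts = 10000) {
  stopifnot(inherits(spec, "cue_spec"))
  b <- .with_seed(seed,
    .generate_cue_batch(1L, spec$mean_target, spec$sd_target,
                        spec$skew_level, max_attempts))
  v <- drop(b$values)
  structure(list(values = v, spec = spec,
                 realized_mean = mean(v), realized_sd = stats::sd(v),
                 realized_skew = b$skew[1L],
                 extreme_index = if (spec$skew_level == "symmetric")
                   NA_integer_ else 10L,
                 extreme_d = b$extreme_d[1L]),
            class = "cue")
}

#' @export
print.cue <- function(x, ...) {
  cat(sprintf("cue distribution [%s, target mean %g, SD %g, %s skew]\n",
              x$spec$modality, x$spec$mean_target, x$spec$sd_target,
              x$spec$skew_level))
  cat("  values:", paste(sprintf("%.1f", x$values), collapse = " "), "\n")
  cat(sprintf("  realized mean %.3f, SD %.3f, G1 skew %.3f\n",
              x$realized_mean, x$realized_sd, x$realized_skew))
  if (!is.na(x$extreme_index))
    cat(sprintf("  extreme element %.1f at %.3f SD from the mean\n",
                x$values[x$extreme_index], x$extreme_d))
  invisible(x)
}

#' Generate cue distributions for every cue trial of a design
#'
#' Vectorized batch version of [generate_cue()]: rows of `design` that carry
#' a cue cell (non-`NA` `cue_mean_level`) receive columns `cue_v1` ..
#' `cue_v10`. For skewed cells the injected extreme element is `cue_v10`.
#'
#' @param design A design table from [enumerate_design()].
#' @param seed Optional integer seed.
#' @param max_attempts Per-cue resampling budget.
#' @return `design` with ten additional cue value columns.
#' @export
generate_cues <- function(design, seed = NULL, max_attempts = 10000) {
  .require_cols(design, c("cue_mean_level", "cue_sd_level", "cue_skew_level"),
                "design table")
  .with_seed(seed, {
    vmat <- matrix(NA_real_, nrow(design), 10L)
    has <- !is.na(design$cue_mean_level)
    if (any(has)) {
      key <- paste(design$cue_mean_level, design$cue_sd_level,
                   design$cue_skew_level)
      for (cell in unique(key[has])) {
        idx <- which(has & key == cell)
        r <- design[idx[1L], ]
        b <- .generate_cue_batch(length(idx), r$cue_mean_level,
                                 r$cue_sd_level, r$cue_skew_level,
                                 max_attempts)
        vmat[idx, ] <- b$values
      }
    }
    colnames(vmat) <- paste0("cue_v", 1:10)
    cbind(design, vmat)
  })
}
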