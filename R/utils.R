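# shared internal helpers

.modalities <- c("pain", "vision")
.tasks <- c("stimulus_response", "expectation", "cued_perception")
.exp_means <- c(30, 40, 50, 60, 70)
.cp_means <- c(30, 70)
.cue_sds <- c(5, 12.5)
.skew_levels <- c("negative", "symmetric", "positive")

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# evaluate expr under a temporary RNG state; NULL seed leaves the stream alone
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic named substream seeds; kept below 2^31 - 1
.substream <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 10007 * as.numeric(offset)) %% 2147483647)
}

.row_max <- function(m) {
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, j])
  out
}

# extract the n x 10 cue value matrix from a trial table
.cue_matrix <- function(trials) {
  cols <- paste0("cue_v", 1:10)
  if (!all(cols %in% names(trials)))
    stop("trial table must contain cue value columns cue_v1..cue_v10")
  as.matrix(trials[, cols])
}

.require_cols <- function(df, cols, what = "trial table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
  invisible(df)
}
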