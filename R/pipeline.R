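# Regressor coding for downstream mixed-model users, and the pipeline
# orchestrator.

#' Build a mixed-model-ready design matrix from a trial table
#'
#' Applies the study's regressor-coding conventions:
#' \itemize{
#'   \item binary factors coded +1 / -1: modality (pain = 1, vision = -1),
#'     and the high vs low level of stimulus intensity, cue mean and cue
#'     variance where the task makes them binary;
#'   \item cue skewness coded as two 0/1 dummies (`skew_negative`,
#'     `skew_positive`) against the symmetric reference;
#'   \item numeric variables (ratings; cue mean and intensity level where
#'     they have more than two levels) z-scored within the table's scope.
#' }
#'
#' @param trials Trial table with the condition columns of its task.
#' @param scope Task scope of the coding: `"expectation"`,
#'   `"cued_perception"` or `"stimulus_response"`; recorded in the result.
#' @return Data frame of coded regressors alongside the identifier columns,
#'   with a `"coding"` attribute recording the z-scoring constants and
#'   level maps (used by [decode_design_matrix()]).
#' @export
build_design_matrix <- function(trials,
                                scope = c("expectation", "cued_perception",
                                          "stimulus_response")) {
  scope <- match.arg(scope)
  .require_cols(trials, "modality")
  if (!all(trials$modality %in% .modalities))
    stop("unknown condition labels in modality: ",
         paste(setdiff(unique(trials$modality), .modalities), collapse = ", "))
  out <- trials[, intersect(c("participant", "block", "mini_block", "trial"),
                            names(trials)), drop = FALSE]
  coding <- list(scope = scope)
  out$modality_code <- ifelse(trials$modality == "pain", 1, -1)
  zscore <- function(x) {
    mu <- mean(x)
    sd_ <- stats::sd(x)
    list(z = (x - mu) / sd_, mean = mu, sd = sd_)
  }
  code_binary <- function(x, what) {
    lev <- sort(unique(x))
    if (length(lev) != 2L)
      stop(sprintf("%s must have exactly 2 levels to be coded +1/-1; found %d",
                   what, length(lev)))
    list(code = ifelse(x == lev[2L], 1, -1), levels = lev)
  }
  if ("intensity_level" %in% names(trials) &&
      !all(is.na(trials$intensity_level))) {
    if (scope == "cued_perception") {
      b <- code_binary(trials$intensity_level, "intensity_level")
      out$intensity_code <- b$code
      coding$intensity_levels <- b$levels
    } else {
      z <- zscore(trials$intensity_level)
      out$intensity_z <- z$z
      coding$intensity <- z[c("mean", "sd")]
    }
  }
  if ("cue_mean_level" %in% names(trials) &&
      !all(is.na(trials$cue_mean_level))) {
    if (scope == "cued_perception") {
      b <- code_binary(trials$cue_mean_level, "cue_mean_level")
      out$cue_mean_code <- b$code
      coding$cue_mean_levels <- b$levels
    } else {
      z <- zscore(trials$cue_mean_level)
      out$cue_mean_z <- z$z
      coding$cue_mean <- z[c("mean", "sd")]
    }
  }
  if ("cue_sd_level" %in% names(trials) && !all(is.na(trials$cue_sd_level))) {
    b <- code_binary(trials$cue_sd_level, "cue_sd_level")
    out$cue_variance_code <- b$code
    coding$cue_sd_levels <- b$levels
  }
  if ("cue_skew_level" %in% names(trials) &&
      !all(is.na(trials$cue_skew_level))) {
    if (!all(trials$cue_skew_level %in% .skew_levels))
      stop("unknown condition labels in cue_skew_level: ",
           paste(setdiff(unique(trials$cue_skew_level), .skew_levels),
                 collapse = ", "))
    out$skew_negative <- as.numeric(trials$cue_skew_level == "negative")
    out$skew_positive <- as.numeric(trials$cue_skew_level == "positive")
  }
  for (rc in intersect(c("rating", "expectation_rating", "perception_rating"),
                       names(trials))) {
    z <- zscore(trials[[rc]])
    out[[paste0(rc, "_z")]] <- z$z
    coding[[rc]] <- z[c("mean", "sd")]
  }
  attr(out, "coding") <- coding
  out
}

#' Decode a coded design matrix back to condition labels
#'
#' Inverts the +1/-1 and dummy codings of [build_design_matrix()] (z-scored
#' continuous covariates are inverted from the recorded constants).
#'
#' @param dm Output of [build_design_matrix()].
#' @return Data frame of reconstructed condition columns.
#' @export
decode_design_matrix <- function(dm) {
  coding <- attr(dm, "coding")
  if (is.null(coding)) stop("not a coded design matrix (no coding attribute)")
  out <- dm[, intersect(c("participant", "block", "mini_block", "trial"),
                        names(dm)), drop = FALSE]
  out$modality <- ifelse(dm$modality_code > 0, "pain", "vision")
  if (!is.null(dm$intensity_code))
    out$intensity_level <- ifelse(dm$intensity_code > 0,
                                  coding$intensity_levels[2L],
                                  coding$intensity_levels[1L])
  if (!is.null(dm$intensity_z))
    out$intensity_level <- dm$intensity_z * coding$intensity$sd +
      coding$intensity$mean
  if (!is.null(dm$cue_mean_code))
    out$cue_mean_level <- ifelse(dm$cue_mean_code > 0,
                                 coding$cue_mean_levels[2L],
                                 coding$cue_mean_levels[1L])
  if (!is.null(dm$cue_mean_z))
    out$cue_mean_level <- dm$cue_mean_z * coding$cue_mean$sd +
      coding$cue_mean$mean
  if (!is.null(dm$cue_variance_code))
    out$cue_sd_level <- ifelse(dm$cue_variance_code > 0,
                               coding$cue_sd_levels[2L],
                               coding$cue_sd_levels[1L])
  if (!is.null(dm$skew_negative))
    out$cue_skew_level <- ifelse(dm$skew_negative == 1, "negative",
                                 ifelse(dm$skew_positive == 1, "positive",
                                        "symmetric"))
  out
}

.pipeline_stages <- c("design", "simulate", "exclude", "fit_expectation",
                      "group_tests", "fit_perception", "compare", "export")

#' Run the end-to-end analysis pipeline on a synthetic cohort
#'
#' Executes the requested stages in dependency order -- simulate ->
#' exclude -> fit expectation -> group tests -> fit perception -> compare
#' -> export design matrices -- writing each requested stage's outputs
#' (CSV tables, JSON reports) plus a `manifest.yaml` listing every written
#' file with its MD5 checksum, the seed and the configuration. Stages not
#' requested but required by a requested stage are computed in memory
#' without writing files. With a fixed seed the outputs and the manifest
#' are byte-identical across runs.
#'
#' @param config Either a [cohort_config()], a list of arguments for it, or
#'   the path to a YAML file holding such a list. An optional `models`
#'   entry (or the `models` argument) selects the observer models.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of
#'   `c("design", "simulate", "exclude", "fit_expectation", "group_tests",`
#'   `"fit_perception", "compare", "export")`.
#' @param models Observer models for the perception stage.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "exclude", "fit_expectation",
                                    "group_tests", "fit_perception",
                                    "compare", "export"),
                         models = c("M1", "M2", "M3", "M4", "M5")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "cohort_config")) {
    if ("models" %in% names(config)) {
      models <- config$models
      config$models <- NULL
    }
    config <- do.call(cohort_config, config)
  }
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(.pipeline_stages, collapse = ", "))
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    files <<- c(files, path)
  }
  res <- list(config = config)
  if ("design" %in% stages) {
    for (task in .tasks) {
      des <- enumerate_design(task, seed = .substream(config$seed, 90))
      if (task != "stimulus_response")
        des <- generate_cues(des, seed = .substream(config$seed, 91))
      emit_csv(des, paste0("design_", task, ".csv"))
    }
  }
  need <- function(stage) any(stages %in%
    .pipeline_stages[match(stage, .pipeline_stages):length(.pipeline_stages)])
  if (need("simulate")) {
    res$cohort <- simulate_cohort(config)
    if ("simulate" %in% stages) {
      emit_csv(res$cohort$truth, "truth.csv")
      emit_csv(res$cohort$calibration_trials, "calibration_trials.csv")
      emit_csv(res$cohort$calibration, "calibration_table.csv")
      emit_csv(res$cohort$expectation_trials, "expectation_trials.csv")
      emit_csv(res$cohort$perception_trials, "perception_trials.csv")
    }
  }
  if (need("exclude")) {
    res$expectation_kept <- exclude_trials(res$cohort$expectation_trials)
    res$perception_kept <- exclude_trials(res$cohort$perception_trials)
    if ("exclude" %in% stages) {
      emit_csv(res$expectation_kept$log, "exclusions_expectation.csv")
      emit_csv(res$perception_kept$log, "exclusions_perception.csv")
    }
  }
  if (need("fit_expectation")) {
    res$expectation_fits <- fit_expectation_cohort(res$expectation_kept$trials)
    if ("fit_expectation" %in% stages)
      emit_csv(res$expectation_fits, "expectation_fits.csv")
  }
  if (need("group_tests") && "group_tests" %in% stages) {
    res$group_tests <- expectation_group_tests(res$expectation_fits)
    emit_json(unclass(res$group_tests), "group_tests.json")
  }
  if (need("fit_perception")) {
    res$perception_fits <- fit_perception_cohort(
      res$perception_kept$trials, res$cohort$calibration,
      expectation_fits = res$expectation_fits, models = models)
    if ("fit_perception" %in% stages) {
      for (m in names(res$perception_fits)) {
        tab <- do.call(rbind, lapply(res$perception_fits[[m]], function(f)
          data.frame(participant = f$participant, model = m,
                     t(f$params), rss = f$rss, n = f$n, aic = f$aic,
                     stringsAsFactors = FALSE)))
        emit_csv(tab, paste0("perception_fits_", m, ".csv"))
      }
    }
  }
  if ("compare" %in% stages) {
    res$comparison <- compare_perception_models(res$perception_fits)
    emit_json(list(aic = res$comparison$aic,
                   group_tests = res$comparison$group_tests,
                   winner_aic = res$comparison$winner_aic,
                   winner_group_f = res$comparison$winner_group_f),
              "comparison.json")
  }
  if ("export" %in% stages) {
    emit_csv(build_design_matrix(res$expectation_kept$trials, "expectation"),
             "design_matrix_expectation.csv")
    emit_csv(build_design_matrix(res$perception_kept$trials,
                                 "cued_perception"),
             "design_matrix_perception.csv")
  }
  manifest <- list(
    package = "distcue",
    version = as.character(utils::packageVersion("distcue")),
    seed = config$seed,
    stages = stages,
    config = lapply(unclass(config), function(x)
      if (is.numeric(x) || is.character(x) || is.logical(x)) x
      else as.character(x)),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
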