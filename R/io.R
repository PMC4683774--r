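# File round-tripping and the config-driven pipeline surface. Everything is
# tidy delimited text (diffable) plus a JSON manifest for run metadata.

#' Read a long-format longitudinal FSH table
#'
#' Tab- or comma-delimited text with a header; required columns
#' \code{subject_id}, \code{age} (decimal years), \code{fsh} (mIU/mL).
#' Lines starting with \code{#} (e.g. a seed provenance comment) are
#' ignored.
#'
#' @param path file path.
#' @return data.frame with the three required columns.
#' @export
read_visits <- function(path) {
  df <- read_delim_auto(path)
  need <- c("subject_id", "age", "fsh")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("longitudinal file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read a one-row-per-subject outcome table
#'
#' Required columns: \code{subject_id}, \code{fmp_age}, \code{censor_age},
#' \code{event}, \code{bmi}, \code{amh}, \code{smoker}, \code{race}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_outcomes <- function(path) {
  df <- read_delim_auto(path)
  need <- c("subject_id", "fmp_age", "censor_age", "event", "bmi", "amh",
            "smoker", "race")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("outcome file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 20)
  first <- first[!startsWith(first, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

write_delim_seed <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic cohort to delimited files
#'
#' Emits \code{visits.tsv}, \code{outcomes.tsv} and \code{truth.tsv} (the
#' ground-truth latents), each carrying the generator seed in a header
#' comment. The first two re-parse with \code{\link{read_visits}} /
#' \code{\link{read_outcomes}}.
#'
#' @param cohort an \code{"fmp_cohort"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fmp_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("visits.tsv", "outcomes.tsv", "truth.tsv"))
  write_delim_seed(cohort$visits, paths[1], cohort$seed)
  write_delim_seed(cohort$outcomes, paths[2], cohort$seed)
  write_delim_seed(cohort$truth, paths[3], cohort$seed)
  invisible(paths)
}

#' Write a coefficient summary table
#'
#' Columns: coefficient, mean, lower and upper 95% bounds, significance
#' flag.
#'
#' @param fit an \code{"fmp_joint"} fit (or its summary).
#' @param path output path (tab-delimited).
#' @export
write_coef_table <- function(fit, path) {
  sm <- if (inherits(fit, "summary.fmp_joint")) fit else summary(fit)
  df <- data.frame(coefficient = rownames(sm$coef), sm$coef,
                   row.names = NULL, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write posterior draws as a delimited chain archive
#'
#' A directory holding tab-delimited chain files (AFT coefficients; scalar
#' GGMM parameters; class labels) and a JSON manifest with config, seed and
#' acceptance-rate provenance.
#'
#' @param fit an \code{"fmp_draws"}/\code{"fmp_joint"} object.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
write_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "fmp_draws"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- fit$draws
  utils::write.table(cbind(iter = seq_len(fit$n_stored), d$gamma),
                     file.path(dir, "chain_aft.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  scal <- cbind(iter = seq_len(fit$n_stored), pi = d$pi, eta = d$eta,
                tau2 = d$tau2, psi2 = d$psi2, lambda2 = d$lambda2,
                sigma2_aft = d$sigma2_aft)
  utils::write.table(scal, file.path(dir, "chain_ggmm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(iter = seq_len(fit$n_stored), d$D),
                     file.path(dir, "chain_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(model = fit$model, K = fit$K, seed = fit$seed,
                   n_stored = fit$n_stored,
                   n_burnin = fit$control$n_burnin,
                   n_draws = fit$control$n_draws, thin = fit$control$thin,
                   acceptance_rate = fit$acceptance_rate,
                   proposal_sd_final = fit$proposal_sd_final)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Default run configuration
#'
#' The serializable configuration consumed by the pipeline entry points
#' \code{\link{run_simulate}}, \code{\link{run_fit}},
#' \code{\link{run_select}}, \code{\link{run_cv}} and
#' \code{\link{run_predict}}. Unknown keys are rejected on read.
#'
#' @return nested named list.
#' @export
fmp_config <- function() {
  list(
    paths = list(longitudinal = "visits.tsv", outcomes = "outcomes.tsv",
                 output_dir = "fmp_out"),
    model = "M2", classes = 2, n_knots = 10, min_visits = 6,
    priors = fmp_priors(),
    sampler = fmp_control(),
    generator = cohort_config(),
    evaluation = list(K_values = c(1, 2, 3), cv_folds = 10,
                      cv_models = c("M0", "M2"), dic = TRUE)
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return \code{read_config}: the validated config list (defaults filled,
#'   unknown keys rejected).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- fmp_config()
  out <- merge_config(def, user, "config")
  for (blk in c("paths", "priors", "sampler", "generator", "evaluation"))
    out[[blk]] <- merge_config(def[[blk]], user[[blk]], blk)
  out
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

run_log <- function(config, outdir, command, extra = list()) {
  log <- c(list(command = command, seed = config$sampler$seed,
                config_hash = config_hash(config),
                n_burnin = config$sampler$n_burnin,
                n_draws = config$sampler$n_draws,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(log, file.path(outdir, paste0(command, "_log.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Pipeline: simulate a cohort to files
#'
#' @param config configuration list (see \code{\link{fmp_config}}).
#' @return invisibly, the cohort object.
#' @export
run_simulate <- function(config = fmp_config()) {
  outdir <- config$paths$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  coh <- simulate_cohort(config$generator, seed = config$sampler$seed)
  write_cohort(coh, outdir)
  run_log(config, outdir, "simulate",
          list(n_subjects = nrow(coh$outcomes),
               n_events = sum(coh$outcomes$event)))
  invisible(coh)
}

#' Pipeline: fit the joint model from files
#'
#' Reads the longitudinal and outcome tables, fits, writes the coefficient
#' table, the chain archive and a structured log; warns if the
#' within-subject-variance Metropolis acceptance rate fell below 5%.
#'
#' @param config configuration list.
#' @return invisibly, the \code{"fmp_joint"} fit.
#' @export
run_fit <- function(config = fmp_config()) {
  outdir <- config$paths$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  visits <- read_visits(config$paths$longitudinal)
  outcomes <- read_outcomes(config$paths$outcomes)
  fit <- fmp_joint(visits, outcomes, model = config$model,
                   K = config$classes, n_knots = config$n_knots,
                   priors = config$priors,
                   control = do.call(fmp_control, config$sampler),
                   min_visits = config$min_visits)
  if (is.finite(fit$acceptance_rate) && fit$acceptance_rate < 0.05)
    warning(sprintf("low Metropolis acceptance rate (%.1f%%): chain may not have converged",
                    100 * fit$acceptance_rate))
  write_coef_table(fit, file.path(outdir, "coefficients.tsv"))
  write_draws(fit, file.path(outdir, "draws"))
  run_log(config, outdir, "fit",
          list(model = fit$model, K = fit$K,
               acceptance_rate = fit$acceptance_rate))
  invisible(fit)
}

#' Pipeline: DIC table over candidate class counts
#'
#' @param config configuration list.
#' @return the DIC data.frame from \code{\link{select_classes}}.
#' @export
run_select <- function(config = fmp_config()) {
  outdir <- config$paths$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  visits <- read_visits(config$paths$longitudinal)
  outcomes <- read_outcomes(config$paths$outcomes)
  tab <- select_classes(visits, outcomes,
                        K_values = config$evaluation$K_values,
                        model = config$model, n_knots = config$n_knots,
                        priors = config$priors,
                        control = do.call(fmp_control, config$sampler),
                        min_visits = config$min_visits)
  utils::write.table(tab, file.path(outdir, "dic_by_K.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  run_log(config, outdir, "select", list(best_K = attr(tab, "best")))
  tab
}

#' Pipeline: cross-validated PMSE comparison of AFT designs
#'
#' @param config configuration list.
#' @return the comparison data.frame from \code{\link{compare_models_cv}}.
#' @export
run_cv <- function(config = fmp_config()) {
  outdir <- config$paths$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  visits <- read_visits(config$paths$longitudinal)
  outcomes <- read_outcomes(config$paths$outcomes)
  tab <- compare_models_cv(visits, outcomes,
                           models = config$evaluation$cv_models,
                           K = config$classes,
                           folds = config$evaluation$cv_folds,
                           control = do.call(fmp_control, config$sampler),
                           n_knots = config$n_knots,
                           priors = config$priors,
                           min_visits = config$min_visits)
  utils::write.table(tab, file.path(outdir, "cv_pmse.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  run_log(config, outdir, "cv", list(models = config$evaluation$cv_models))
  tab
}

#' Pipeline: fit and predict FMP age for new subjects
#'
#' Fits the configured model (the simplified prediction model
#' \code{"Mfinal"} by default if \code{config$model} is not set otherwise)
#' and predicts FMP ages with 95% credible intervals for the supplied
#' subjects.
#'
#' @param config configuration list.
#' @param newdata data.frame as for \code{\link{predict.fmp_joint}}.
#' @param model model id used for prediction (default "Mfinal").
#' @return data.frame of predictions.
#' @export
run_predict <- function(config = fmp_config(), newdata, model = "Mfinal") {
  outdir <- config$paths$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  visits <- read_visits(config$paths$longitudinal)
  outcomes <- read_outcomes(config$paths$outcomes)
  fit <- fmp_joint(visits, outcomes, model = model, K = config$classes,
                   n_knots = config$n_knots, priors = config$priors,
                   control = do.call(fmp_control, config$sampler),
                   min_visits = config$min_visits)
  pred <- cbind(newdata, predict(fit, newdata))
  utils::write.table(pred, file.path(outdir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  run_log(config, outdir, "predict", list(model = model, n_new = nrow(pred)))
  pred
}
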