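## End-to-end orchestration of the two-step analysis: simulate (optional)
## -> stage-1 offset GLM -> out-of-bootstrap mstop -> boosting ->
## stability selection -> browsing smoothing -> DVC index and risk classes
## -> harvest validation.

#' Pipeline configuration
#'
#' Bundles the landscape generator configuration with all stage
#' parameters. Defaults follow the package's reference settings; every
#' parameter is exposed.
#'
#' @param landscape a \code{\link{landscape_config}}.
#' @param nu boosting step length.
#' @param mstop_grid candidate iteration grid for out-of-bootstrap
#'   selection.
#' @param n_boot bootstrap replicates for mstop selection.
#' @param n_subsamples stability-selection half-samples.
#' @param threshold stability-selection frequency threshold.
#' @param target_df common effective df of the base-learners.
#' @param browsing_target_df hat-trace target of the browsing smoother
#'   (default: districts / 4).
#' @param k_classes number of risk classes.
#' @param span LOWESS span for the harvest validation.
#' @param seed master seed for the stochastic stages (bootstrap,
#'   subsampling, k-means restarts).
#' @param verbose print stage progress to stderr.
#' @return Object of class \code{"dvc_pipeline_config"}.
#' @export
pipeline_config <- function(landscape = landscape_config(),
                            nu = 0.1,
                            mstop_grid = seq(0L, 1500L, by = 25L),
                            n_boot = 25L,
                            n_subsamples = 50L,
                            threshold = 0.5,
                            target_df = 4,
                            browsing_target_df = NULL,
                            k_classes = 7L,
                            span = 2 / 3,
                            seed = 1L,
                            verbose = FALSE) {
  if (!inherits(landscape, "dvc_config"))
    stop_config("landscape must be a landscape_config()")
  if (nu <= 0 || nu > 1) stop_config("nu must lie in (0, 1]")
  if (threshold <= 0 || threshold > 1)
    stop_config("threshold must lie in (0, 1]")
  structure(list(landscape = landscape, nu = nu,
                 mstop_grid = as.integer(mstop_grid),
                 n_boot = as.integer(n_boot),
                 n_subsamples = as.integer(n_subsamples),
                 threshold = threshold, target_df = target_df,
                 browsing_target_df = browsing_target_df,
                 k_classes = as.integer(k_classes), span = span,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "dvc_pipeline_config")
}

config_hash <- function(config) {
  dvc_hash(utils::capture.output(utils::str(config, digits.d = 15)))
}

#' Run the full analysis pipeline
#'
#' Simulates the synthetic world, fits the mandatory stage-1 offset GLM,
#' selects the number of boosting iterations by out-of-bootstrap risk,
#' fits the boosted additive model, runs stability selection, smooths the
#' browsing survey over the district graph (replacing the municipality
#' browsing covariates by the centroid-extracted smooth estimates before
#' boosting), computes and classifies the DVC index and validates it
#' against simulated harvest densities.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory; when given, all stage artifacts
#'   (tables, fitted model, report) are written there.
#' @return Object of class \code{"dvc_report"}: every stage result plus a
#'   machine-readable summary (config hash, seed, selected mstop, stable
#'   learners with frequencies, index summary, Spearman rho).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "dvc_pipeline_config"))
  say <- function(...) if (config$verbose)
    message(sprintf("[dvcrisk] %s", sprintf(...)))
  lc <- config$landscape

  say("simulate: landscape %d x %d", lc$grid_rows, lc$grid_cols)
  land <- generate_landscape(lc)
  collisions <- simulate_collisions(land$munis, lc)
  survey <- simulate_browsing_survey(land$graph, lc)
  truth_index <- true_dvc_index(land$munis, lc, year = 2006L)
  harvest <- simulate_harvest(land$munis, truth_index, lc)

  say("browsing: MRF smoothing over %d districts", length(land$graph$nodes))
  mrf <- fit_mrf_binomial(survey, land$graph,
                          target_df = config$browsing_target_df)
  munis <- land$munis
  sm <- extract_at_centroids(mrf, munis)
  for (cl in setdiff(names(sm), "muni_id")) munis[[cl]] <- sm[[cl]]

  say("fit-offset: stage-1 Poisson GLM")
  offset_fit <- fit_offset_glm(collisions)
  offs <- stage1_offset(offset_fit, collisions)
  data <- boost_data(collisions, munis)
  learners <- default_learners(target_df = config$target_df)

  say("oob: %d bootstrap replicates, grid up to %d", config$n_boot,
      max(config$mstop_grid))
  oob <- select_mstop_oob(data, offs, learners, nu = config$nu,
                          grid = config$mstop_grid,
                          n_boot = config$n_boot, seed = config$seed)

  say("boost: mstop = %d", oob$mstop)
  fit <- fit_boost(data, offs, learners, nu = config$nu,
                   mstop = oob$mstop)

  say("stability: %d subsamples at m_iter = %d", config$n_subsamples,
      max(oob$mstop, 1L))
  stab <- stability_select(data, offs, learners, nu = config$nu,
                           m_iter = max(oob$mstop, 1L),
                           n_subsamples = config$n_subsamples,
                           threshold = config$threshold,
                           seed = config$seed)

  say("index: %d stable learners", length(stab$selected))
  index <- compute_index(fit, munis, year = 2006L,
                         selected = stab$selected)
  classes <- tryCatch(
    classify_risk(index, k = config$k_classes, seed = config$seed),
    error = function(e) NULL)

  say("validate: harvest correlation")
  validation <- validate_against_harvest(index, munis, harvest,
                                         span = config$span)

  summary <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_municipalities = nrow(munis),
    n_collision_rows = nrow(collisions),
    stage1_coefficients = as.list(round(coef(offset_fit), 6)),
    selected_mstop = oob$mstop,
    stable_learners = as.list(round(
      stab$frequency[order(-stab$frequency)], 3)),
    selected_set = stab$selected,
    index_summary = list(mean = mean(index$index), sd = stats::sd(index$index),
                         min = min(index$index), max = max(index$index)),
    spearman_rho = validation$rho,
    spearman_p = validation$p_value)

  report <- structure(
    list(config = config, landscape = land, collisions = collisions,
         survey = survey, harvest = harvest, browsing = mrf,
         munis = munis, offset_fit = offset_fit, offset = offs,
         oob = oob, fit = fit, stability = stab, index = index,
         classes = classes, validation = validation, summary = summary),
    class = "dvc_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_landscape(report$landscape, out_dir)
  write_table_csv(report$collisions, file.path(out_dir, "collisions.csv"))
  write_table_csv(report$survey, file.path(out_dir, "browsing_survey.csv"))
  write_table_csv(report$harvest, file.path(out_dir, "harvest.csv"))
  props <- data.frame(district_id = rownames(report$browsing$proportions),
                      report$browsing$proportions, row.names = NULL)
  write_table_csv(props, file.path(out_dir, "browsing_smoothed.csv"))
  st1 <- data.frame(term = names(coef(report$offset_fit)),
                    estimate = as.numeric(coef(report$offset_fit)),
                    se = sqrt(diag(report$offset_fit$vcov)))
  write_table_csv(st1, file.path(out_dir, "stage1_coefficients.csv"))
  write_table_csv(stratum_rate_table(report$offset_fit),
                  file.path(out_dir, "stage1_rates.csv"))
  write_table_csv(data.frame(mstop = report$oob$grid,
                             mean_risk = report$oob$mean_risk),
                  file.path(out_dir, "oob_risk.csv"))
  write_table_csv(data.frame(learner = names(report$stability$frequency),
                             frequency = report$stability$frequency),
                  file.path(out_dir, "stability_frequencies.csv"))
  idx <- as.data.frame(report$index)
  if (!is.null(report$classes))
    idx$risk_class <- report$classes$classes$class[
      match(idx$muni_id, report$classes$classes$muni_id)]
  write_table_csv(idx, file.path(out_dir, "dvc_index.csv"))
  write_table_csv(report$validation$table,
                  file.path(out_dir, "validation_table.csv"))
  write_table_csv(report$validation$curve,
                  file.path(out_dir, "lowess_curve.csv"))
  write_boost_fit(report$fit, file.path(out_dir, "boost_fit.json"))
  jsonlite::write_json(report$summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.dvc_report <- function(x, ...) {
  s <- x$summary
  cat("DVC risk pipeline report\n")
  cat(sprintf("  config %s, seed %d: %d municipalities, %d collision rows\n",
              s$config_hash, s$seed, s$n_municipalities, s$n_collision_rows))
  cat(sprintf("  selected mstop: %d; stable learners: %s\n",
              s$selected_mstop,
              if (length(s$selected_set))
                paste(s$selected_set, collapse = ", ") else "(none)"))
  cat(sprintf("  index: mean %.3f (sd %.3f, range %.3f..%.3f)\n",
              s$index_summary$mean, s$index_summary$sd,
              s$index_summary$min, s$index_summary$max))
  cat(sprintf("  harvest validation: Spearman rho %.3f (p = %.3g)\n",
              s$spearman_rho, s$spearman_p))
  invisible(x)
}
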