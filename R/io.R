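## Flat-file interchange: CSV tables with documented headers, YAML
## configuration, JSON model/report files.

read_csv_checked <- function(path, required, file_label) {
  if (!file.exists(path))
    stop_validation(file_label, " file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop_validation(file_label, " (", path, ") lacks columns: ",
                    paste(miss, collapse = ", "))
  d
}

check_numeric_cols <- function(d, cols, file_label) {
  for (cl in cols)
    if (!is.numeric(d[[cl]]))
      stop_validation(file_label, ": column ", cl, " is not numeric")
  invisible(d)
}

#' Read and write the pipeline's tables
#'
#' CSV readers with schema validation (missing columns, non-numeric
#' cells, duplicate municipality ids, zero-length road rows, impossible
#' browsing counts are rejected with explicit messages) and matching
#' writers. The district graph travels as a two-column edge list.
#'
#' @param path file path.
#' @name dvc_io
#' @return The validated table (readers) or the path, invisibly (writers).
NULL

#' @rdname dvc_io
#' @export
read_municipalities <- function(path) {
  d <- read_csv_checked(path, c("muni_id", "centroid_x", "centroid_y",
                                "district_id", "red_deer",
                                paste0("len_", road_types())),
                        "municipality table")
  check_numeric_cols(d, c("centroid_x", "centroid_y",
                          paste0("len_", road_types())),
                     "municipality table")
  if (anyDuplicated(d$muni_id))
    stop_validation("municipality table: duplicate muni_id")
  if (anyDuplicated(d[, c("centroid_x", "centroid_y")]))
    stop_validation("municipality table: centroids not unique")
  if (any(sapply(d[paste0("len_", road_types())], function(x) any(x < 0))))
    stop_validation("municipality table: negative road length")
  d$red_deer <- as.logical(d$red_deer)
  for (cl in intersect(browsing_classes(), names(d)))
    if (any(d[[cl]] < 0 | d[[cl]] > 1))
      stop_validation("municipality table: browsing proportions outside [0, 1]")
  d
}

#' @rdname dvc_io
#' @export
read_collisions <- function(path) {
  d <- read_csv_checked(path, c("muni_id", "road_type", "year", "count",
                                "road_length", "red_deer"),
                        "collision table")
  check_numeric_cols(d, c("year", "count", "road_length"),
                     "collision table")
  d$red_deer <- as.logical(d$red_deer)
  d$year <- as.integer(d$year)
  d$count <- as.integer(d$count)
  validate_collision_table(d)
  d
}

#' @rdname dvc_io
#' @export
read_survey <- function(path) {
  d <- read_csv_checked(path, c("district_id", "palatability_class",
                                "n_examined", "n_browsed"),
                        "sapling survey")
  check_numeric_cols(d, c("n_examined", "n_browsed"), "sapling survey")
  validate_survey(d)
  d
}

#' @rdname dvc_io
#' @export
read_edges <- function(path) {
  d <- read_csv_checked(path, c("from", "to"), "district edge list")
  if (any(d$from == d$to))
    stop_validation("district edge list: self-loops not allowed")
  d
}

#' @rdname dvc_io
#' @export
read_harvest <- function(path) {
  d <- read_csv_checked(path, c("district_id", "harvest_per_100ha"),
                        "harvest table")
  check_numeric_cols(d, "harvest_per_100ha", "harvest table")
  if (any(d$harvest_per_100ha < 0))
    stop_validation("harvest table: negative harvest density")
  d
}

#' @rdname dvc_io
#' @param x table (or landscape / graph object) to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname dvc_io
#' @param land a \code{\link{generate_landscape}} result.
#' @param dir output directory (created if needed).
#' @export
write_landscape <- function(land, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(land$munis, file.path(dir, "municipalities.csv"))
  write_table_csv(land$graph$edges, file.path(dir, "district_edges.csv"))
  invisible(dir)
}

#' Serialize and restore a boosted fit
#'
#' The fitted ensemble travels as JSON: learner specifications, aggregated
#' coefficients, knots, penalties' ridge amounts, centering constants and
#' the selection path. Restoring requires the training data (to rebuild
#' the design matrices exactly).
#'
#' @param fit a \code{"dvc_boost"} object.
#' @param path JSON file path.
#' @export
write_boost_fit <- function(fit, path) {
  payload <- list(
    nu = fit$nu, mstop = fit$mstop,
    selection_path = fit$selection_path,
    intercept = fit$intercept,
    centering = as.list(fit$centering),
    learners = lapply(fit$learners, unclass),
    coefficients = fit$coefficients,
    lambda = lapply(fit$designs, `[[`, "lambda"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_boost_fit
#' @param data the training model frame (see \code{\link{boost_data}}).
#' @param offset the training offset vector.
#' @export
read_boost_fit <- function(path, data, offset) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  learners <- lapply(p$learners, function(s) do.call(new_bl_spec, s))
  fit <- fit_boost(data, offset, learners, nu = p$nu, mstop = 0L)
  fit$coefficients <- lapply(p$coefficients, as.numeric)
  names(fit$coefficients) <- vapply(learners, `[[`, "", "name")
  fit$selection_path <- as.integer(p$selection_path)
  fit$mstop <- as.integer(p$mstop)
  fit$centering <- unlist(p$centering)
  fit$intercept <- p$intercept
  ## rebuild the training linear predictor from the restored coefficients
  eta <- offset
  for (j in seq_along(fit$designs)) {
    d <- fit$designs[[j]]
    eta <- eta + if (d$spec$kind == "random_intercept")
      fit$coefficients[[j]] else drop(d$B %*% fit$coefficients[[j]])
  }
  fit$F <- eta
  fit
}

#' Pipeline configuration files
#'
#' The pipeline configuration is the landscape configuration plus the
#' stage parameters (boosting step length and grid, bootstrap and
#' subsample counts, selection threshold, smoothing df, class count,
#' LOWESS span). Stored as YAML.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  ser <- unclass(config)
  ser$landscape <- unclass(ser$landscape)
  ser$landscape$true_effects <- as.list(ser$landscape$true_effects)
  ser$landscape$road_length_params <-
    as.list(ser$landscape$road_length_params)
  ser$landscape$browsing_params <- as.list(ser$landscape$browsing_params)
  ser$landscape$p_no_road <- as.list(ser$landscape$p_no_road)
  ser$landscape$true_beta <- as.list(ser$landscape$true_beta)
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  y <- yaml::read_yaml(path)
  lc <- y$landscape
  lc$true_effects <- as.data.frame(lc$true_effects)
  lc$road_length_params <- as.data.frame(lc$road_length_params)
  lc$browsing_params <- as.data.frame(lc$browsing_params)
  lc$p_no_road <- unlist(lc$p_no_road)
  lc$true_beta <- unlist(lc$true_beta)
  land <- do.call(landscape_config, lc)
  args <- y[setdiff(names(y), "landscape")]
  do.call(pipeline_config, c(list(landscape = land), args))
}
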