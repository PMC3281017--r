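## Stage 1: mandatory parametric Poisson model of collision counts with
## log road length as offset; road type x survey year interactions and a
## red-deer-district indicator, all under treatment coding (reference:
## residential streets in 2006 outside red-deer districts).

validate_collision_table <- function(collisions) {
  need <- c("muni_id", "road_type", "year", "count", "road_length")
  miss <- setdiff(need, names(collisions))
  if (length(miss))
    stop_validation("collision table lacks columns: ",
                    paste(miss, collapse = ", "))
  if (!"red_deer" %in% names(collisions))
    stop_validation("collision table lacks the red_deer indicator")
  if (any(collisions$count < 0))
    stop_validation("negative collision counts")
  if (any(collisions$count != round(collisions$count)))
    stop_validation("non-integer collision counts")
  if (any(collisions$road_length <= 0))
    stop_validation("rows with road_length <= 0 are not allowed; ",
                    "omit municipality/road-type pairs without that road")
  bad <- setdiff(unique(collisions$road_type), road_types())
  if (length(bad))
    stop_validation("unknown road types: ", paste(bad, collapse = ", "))
  if (!all(collisions$year %in% survey_years()))
    stop_validation("year must be one of ",
                    paste(survey_years(), collapse = ", "))
  invisible(collisions)
}

offset_frame <- function(collisions) {
  data.frame(
    count = collisions$count,
    road_type = factor(collisions$road_type,
                       levels = c("residential",
                                  setdiff(road_types(), "residential"))),
    year = factor(collisions$year, levels = survey_years()),
    red_deer = as.numeric(collisions$red_deer),
    road_length = collisions$road_length)
}

#' Fit the mandatory parametric offset model
#'
#' Maximum-likelihood Poisson regression of collision counts on road type,
#' survey year, their interaction and the red-deer-district indicator, with
#' the log road length as offset (coefficient fixed at one). Fitting uses
#' iteratively reweighted least squares (via \code{stats::glm}, convergence
#' tolerance 1e-14); the covariance is the inverse Fisher information.
#'
#' @param collisions long-format collision table with columns
#'   \code{muni_id}, \code{road_type}, \code{year}, \code{count},
#'   \code{road_length} (> 0) and \code{red_deer}.
#' @return Object of class \code{"dvc_offset_fit"}: \code{coefficients}
#'   (11 named values under treatment coding), \code{vcov},
#'   \code{log_likelihood}, \code{reference_levels}, and the underlying
#'   \code{glm} fit.
#' @examples
#' toy <- data.frame(muni_id = c("a", "b"), road_type = "residential",
#'                   year = 2006L, count = c(3L, 5L),
#'                   road_length = c(1, 3), red_deer = FALSE)
#' fit <- fit_offset_glm(toy)
#' exp(coef(fit)[["(Intercept)"]])  # total count / total length = 2
#' @export
fit_offset_glm <- function(collisions) {
  validate_collision_table(collisions)
  d <- offset_frame(collisions)
  d <- droplevels(d)
  ## degenerate strata (toy tables spanning a single level) drop the
  ## corresponding terms; full data yields the 11-parameter model
  rhs <- c(if (nlevels(d$road_type) > 1) "road_type",
           if (nlevels(d$year) > 1) "year",
           if (nlevels(d$road_type) > 1 && nlevels(d$year) > 1)
             "road_type:year",
           if (length(unique(d$red_deer)) > 1) "red_deer")
  fml <- stats::reformulate(c("1", rhs, "offset(log(road_length))"),
                            response = "count")
  fit <- stats::glm(fml, family = stats::poisson(link = "log"), data = d,
                    control = stats::glm.control(epsilon = 1e-14,
                                                 maxit = 100))
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop_numeric("inestimable stratum; no data for: ",
                 paste(bad, collapse = ", "))
  }
  structure(list(coefficients = cf,
                 vcov = stats::vcov(fit),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 reference_levels = list(road_type = "residential",
                                         year = "2006", red_deer = FALSE),
                 glm = fit),
            class = "dvc_offset_fit")
}

#' @export
coef.dvc_offset_fit <- function(object, ...) object$coefficients

#' @export
vcov.dvc_offset_fit <- function(object, ...) object$vcov

#' @export
logLik.dvc_offset_fit <- function(object, ...)
  stats::logLik(object$glm)

#' @export
print.dvc_offset_fit <- function(x, ...) {
  cat("Parametric Poisson offset model (stage 1)\n")
  cat(sprintf("  %d coefficients, log-likelihood %.2f\n",
              length(x$coefficients), x$log_likelihood))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Expected collisions per kilometer by stratum
#'
#' The stage-1 fitted rate per km and year for given road type, survey
#' year and red-deer status: \code{exp} of the linear predictor without
#' the offset. The red-deer indicator acts as a multiplicative factor on
#' the rate.
#'
#' @param fit a \code{\link{fit_offset_glm}} result.
#' @param road_type,year,red vectors of stratum levels (recycled).
#' @return Numeric vector of expected collisions per km per year.
#' @export
expected_dvc_per_km <- function(fit, road_type, year, red = FALSE) {
  n <- max(length(road_type), length(year), length(red))
  road_type <- rep_len(as.character(road_type), n)
  year <- rep_len(as.character(year), n)
  red <- rep_len(red, n)
  bad <- setdiff(road_type, road_types())
  if (length(bad))
    stop_validation("unknown road type: ", paste(bad, collapse = ", "))
  if (!all(year %in% as.character(survey_years())))
    stop_validation("unknown year level")
  nd <- data.frame(
    road_type = factor(road_type, levels = levels(fit$glm$data$road_type)),
    year = factor(year, levels = levels(fit$glm$data$year)),
    red_deer = as.numeric(red),
    road_length = 1)
  ## offset(log(1)) = 0, so the prediction is the stratum rate per km
  as.numeric(stats::predict(fit$glm, newdata = nd, type = "response"))
}

#' Stratum rate table
#'
#' Expected collisions per km for every road type, year and red-deer
#' status combination present in the model.
#'
#' @param fit a \code{\link{fit_offset_glm}} result.
#' @return Data frame with one row per stratum and the fitted rate.
#' @export
stratum_rate_table <- function(fit) {
  g <- expand.grid(road_type = road_types(),
                   year = survey_years(), red_deer = c(FALSE, TRUE),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$dvc_per_km <- expected_dvc_per_km(fit, g$road_type, g$year, g$red_deer)
  g
}

#' Stage-1 offset for the boosting stage
#'
#' Per-row offset \code{log(road_length) + } stage-1 linear predictor, so
#' that \code{exp(offset)} equals the stage-1 fitted mean. This whole
#' predictor enters stage 2 with coefficient fixed at one.
#'
#' @param fit a \code{\link{fit_offset_glm}} result.
#' @param collisions collision table whose levels are known to the fit.
#' @return Numeric offset vector, one value per row.
#' @export
stage1_offset <- function(fit, collisions) {
  validate_collision_table(collisions)
  nd <- offset_frame(collisions)
  as.numeric(stats::predict(fit$glm, newdata = nd, type = "link"))
}
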