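## Simulate collision counts from the two-stage model: stage-1 parametric
## log-rates (road type x year, red deer) with log road length as offset,
## plus sparse nonlinear covariate effects, a smooth spatial surface, an
## optional 2009-only spatio-temporal surface and lognormal overdispersion.

## Centered effect shapes on [0, 1] used by the generator (and as ground
## truth in recovery tests). Shapes are applied to the covariate rescaled
## to its observed range across municipalities, so an effect's amplitude
## is realized over the range the covariate actually spans.
effect_input <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
}

effect_function <- function(fun, amplitude) {
  switch(fun,
         sin = function(x) amplitude * sin(2 * pi * x),
         quadratic = function(x) amplitude * ((2 * x - 1)^2 - 1 / 3),
         monotone = function(x)
           amplitude * (stats::plogis(10 * (x - 0.5)) - 0.5),
         linear = function(x) amplitude * (x - 0.5),
         stop_config("unknown effect function tag: ", fun))
}

## Deterministic smooth surfaces of normalized centroid coordinates.
spatial_surface <- function(x01, y01, amplitude) {
  amplitude * cos(pi * x01) * cos(pi * y01)
}

spacetime_surface <- function(x01, y01, amplitude) {
  amplitude * sin(pi * x01) * sin(pi * y01)
}

## Stage-1 linear predictor (without offset) from the named 11-vector.
stage1_eta <- function(beta, road_type, year, red_deer) {
  eta <- rep(beta[["intercept"]], length(road_type))
  for (rt in setdiff(road_types(), "residential")) {
    is_rt <- road_type == rt
    eta[is_rt] <- eta[is_rt] + beta[[paste0("road_", rt)]]
    eta[is_rt & year == 2009L] <- eta[is_rt & year == 2009L] +
      beta[[paste0("road_", rt, ":year2009")]]
  }
  eta[year == 2009L] <- eta[year == 2009L] + beta[["year2009"]]
  eta[red_deer] <- eta[red_deer] + beta[["red_deer"]]
  eta
}

#' Simulate collision counts on the synthetic landscape
#'
#' For every municipality, road category with positive length, and survey
#' year, draws \code{count ~ Poisson(length * exp(eta))} where \code{eta}
#' is the stage-1 linear predictor plus the configured true partial
#' functions of the covariates, the spatial surface, the 2009-only
#' spatio-temporal surface, and a lognormal observation intercept.
#' Municipality/road-type pairs without that road type are omitted
#' (structural zeros are not rows).
#'
#' @param munis municipality table from \code{\link{generate_landscape}}.
#' @param config the \code{\link{landscape_config}} used to generate it.
#' @return Long-format collision table (\code{muni_id}, \code{road_type},
#'   \code{year}, \code{count}, \code{road_length}, \code{red_deer}) with
#'   the per-row ground truth attached as attribute \code{"truth"}: a data
#'   frame with the total \code{eta} and its additive components
#'   (\code{eta_stage1}, one \code{f_<covariate>} per true effect,
#'   \code{eta_spatial}, \code{eta_spacetime}, \code{b_overdispersion}).
#' @examples
#' land <- generate_landscape(landscape_config(grid_rows = 4, grid_cols = 4,
#'                                             district_block = 2))
#' coll <- simulate_collisions(land$munis, land$config)
#' head(coll)
#' @export
simulate_collisions <- function(munis, config) {
  validate_config(config)
  te <- config$true_effects
  bad <- setdiff(te$covariate, names(munis))
  if (length(bad))
    stop_config("true_effects references unknown covariates: ",
                paste(bad, collapse = ", "))

  rows <- do.call(rbind, lapply(road_types(), function(rt) {
    len <- munis[[paste0("len_", rt)]]
    keep <- len > 0
    if (!any(keep)) return(NULL)
    do.call(rbind, lapply(survey_years(), function(yr) {
      data.frame(muni_id = munis$muni_id[keep], road_type = rt, year = yr,
                 road_length = len[keep],
                 red_deer = munis$red_deer[keep],
                 mi = which(keep))
    }))
  }))
  rows <- rows[order(rows$muni_id, rows$road_type, rows$year), ]
  rownames(rows) <- NULL
  mi <- rows$mi
  rows$mi <- NULL

  truth <- data.frame(
    eta_stage1 = stage1_eta(config$true_beta, rows$road_type, rows$year,
                            rows$red_deer))
  for (k in seq_len(nrow(te))) {
    f <- effect_function(te$fun[k], te$amplitude[k])
    truth[[paste0("f_", te$covariate[k])]] <-
      f(effect_input(munis[[te$covariate[k]]])[mi])
  }
  x01 <- munis$centroid_x[mi] / config$grid_cols
  y01 <- munis$centroid_y[mi] / config$grid_rows
  truth$eta_spatial <- spatial_surface(x01, y01, config$spatial_amplitude)
  truth$eta_spacetime <- ifelse(rows$year == 2009L,
                                spacetime_surface(x01, y01,
                                                  config$spacetime_amplitude),
                                0)
  with_seed(stream_seed(config$seed, "collisions"), {
    truth$b_overdispersion <- stats::rnorm(nrow(rows), 0,
                                           config$overdispersion_sd)
    truth$eta <- rowSums(truth)
    rows$count <- stats::rpois(nrow(rows),
                               rows$road_length * exp(truth$eta))
  })
  attr(rows, "truth") <- truth
  rows
}

#' True partial effect of a covariate
#'
#' Evaluates one configured true effect at given covariate values (which
#' are rescaled by the covariate's observed range across municipalities,
#' the scale the generator applies the shape on).
#'
#' @inheritParams simulate_collisions
#' @param covariate name of a covariate listed in the configured true
#'   effects.
#' @param values covariate values at which to evaluate.
#' @return Numeric vector of true contributions on the log-rate scale.
#' @export
true_partial <- function(munis, config, covariate, values) {
  te <- config$true_effects
  k <- match(covariate, te$covariate)
  if (is.na(k)) stop_validation("no true effect for ", covariate)
  r <- range(munis[[covariate]])
  f <- effect_function(te$fun[k], te$amplitude[k])
  f(pmin(pmax((values - r[1]) / (r[2] - r[1]), 0), 1))
}

#' True DVC index of the generator
#'
#' The exponentiated sum of the configured true partial functions and the
#' spatial surface (plus, for 2009, the spatio-temporal surface) per
#' municipality: the quantity the fitted DVC index estimates.
#'
#' @inheritParams simulate_collisions
#' @param year survey year (2006 or 2009).
#' @return Named numeric vector of true indices, one per municipality.
#' @export
true_dvc_index <- function(munis, config, year = 2006L) {
  te <- config$true_effects
  eta <- numeric(nrow(munis))
  for (k in seq_len(nrow(te))) {
    f <- effect_function(te$fun[k], te$amplitude[k])
    eta <- eta + f(effect_input(munis[[te$covariate[k]]]))
  }
  x01 <- munis$centroid_x / config$grid_cols
  y01 <- munis$centroid_y / config$grid_rows
  eta <- eta + spatial_surface(x01, y01, config$spatial_amplitude)
  if (year == 2009L)
    eta <- eta + spacetime_surface(x01, y01, config$spacetime_amplitude)
  stats::setNames(exp(eta), munis$muni_id)
}
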