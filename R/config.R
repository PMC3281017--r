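#' Configuration of the synthetic landscape generator
#'
#' Assembles (and validates) the full parameterization of the synthetic
#' world: a rectangular grid of municipalities partitioned into square
#' game-management districts, lognormal road-length distributions for the
#' five road categories, spatially autocorrelated environmental covariates,
#' a sparse set of true nonlinear covariate effects on the collision rate,
#' a smooth spatial surface, lognormal overdispersion, district-level
#' browsing fields and a saturating harvest-index relation.
#'
#' The defaults define the reference study conditions used throughout the
#' package's tests: a 20 x 20 municipality grid in 2 x 2 district blocks
#' (100 districts; municipality-to-district ratio close to the Bavarian
#' one),
#' road-presence probabilities and length distributions ordered as
#' residential >> tertiary > secondary > primary > motorway, a strongly
#' negative motorway contrast (fencing), a red-deer rate factor of 0.76, a
#' uniform +15\% year-2009 effect, and 6 true covariate effects (3 climate,
#' 2 land use, 1 monotone browsing) out of 23 covariates.
#'
#' @param grid_rows,grid_cols positive integers (>= 2); the municipality
#'   grid. Municipality count is \code{grid_rows * grid_cols}.
#' @param district_block positive integer dividing both grid dimensions;
#'   districts are \code{district_block x district_block} blocks of cells.
#' @param seed integer; master seed. All generators draw from substreams
#'   derived from it.
#' @param road_length_params data frame with columns \code{road_type},
#'   \code{meanlog}, \code{sdlog}: lognormal length distribution (km) per
#'   road category.
#' @param p_no_road named numeric in [0, 1): probability that a
#'   municipality lacks a given road category entirely.
#' @param covariate_spatial_range correlation length (grid units) of the
#'   Gaussian random fields behind the covariates.
#' @param covariate_nugget fraction (in [0, 1]) of independent noise mixed
#'   into each covariate field.
#' @param overdispersion_sd standard deviation of the log-scale
#'   observation-specific random intercepts.
#' @param true_effects data frame with columns \code{covariate},
#'   \code{fun} (one of \code{"sin"}, \code{"quadratic"},
#'   \code{"monotone"}, \code{"linear"}) and \code{amplitude}; covariates
#'   not listed have no effect (pure noise). Shapes are applied to the
#'   covariate rescaled to its observed range, so the amplitude is
#'   realized over the range the covariate actually spans (see
#'   \code{\link{true_partial}}).
#' @param true_beta named numeric of length 11: stage-1 coefficients under
#'   treatment coding (reference: residential streets, year 2006, outside
#'   red-deer districts). Names: \code{intercept},
#'   \code{road_<type>} for the four non-reference types, \code{year2009},
#'   \code{road_<type>:year2009}, \code{red_deer}.
#' @param spatial_amplitude amplitude of the smooth spatial surface on the
#'   log-rate scale.
#' @param spacetime_amplitude amplitude of the 2009-only spatio-temporal
#'   surface (default 0: the year effect is purely global).
#' @param browsing_params data frame with columns \code{class},
#'   \code{base_logit}, \code{amplitude}: per palatability class the
#'   baseline browsing logit and the amplitude of its district-level
#'   spatial field.
#' @param browsing_spatial_range correlation length (district units) of the
#'   browsing fields.
#' @param browsing_nugget_sd standard deviation (logit scale) of the
#'   unstructured district-level component of the browsing fields: local
#'   deer-density variation among districts beyond the regional trend.
#' @param browsing_drop_fraction fraction of district x class survey cells
#'   dropped to emulate locally absent genera; a single value or a vector
#'   named by palatability class.
#' @param saplings_per_district number of saplings examined per district,
#'   class and year (survey transects examine 75 saplings per point).
#' @param harvest_params list with \code{hmax}, \code{half_sat},
#'   \code{noise_sd}: district harvest per 100 ha is
#'   \code{hmax * I / (half_sat + I)} at district-mean true index \code{I},
#'   times mean-one lognormal noise. The saturating form plateaus for high
#'   index values.
#'
#' @return An object of class \code{"dvc_config"} (a validated list).
#' @examples
#' cfg <- landscape_config(grid_rows = 6, grid_cols = 6, district_block = 3)
#' land <- generate_landscape(cfg)
#' nrow(land$munis)
#' @export
landscape_config <- function(grid_rows = 20L,
                             grid_cols = 20L,
                             district_block = 2L,
                             seed = 2006L,
                             road_length_params = default_road_lengths(),
                             p_no_road = c(motorway = 0.8, primary = 0.5,
                                           secondary = 0.25, tertiary = 0.1,
                                           residential = 0.02),
                             covariate_spatial_range = 4,
                             covariate_nugget = 0.3,
                             overdispersion_sd = 0.2,
                             true_effects = default_true_effects(),
                             true_beta = default_true_beta(),
                             spatial_amplitude = 0.3,
                             spacetime_amplitude = 0,
                             browsing_params = default_browsing_params(),
                             browsing_spatial_range = 2,
                             browsing_nugget_sd = 0.4,
                             browsing_drop_fraction = 0.1,
                             saplings_per_district = 75L,
                             harvest_params = list(hmax = 12, half_sat = 0.8,
                                                   noise_sd = 0.25)) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              district_block = as.integer(district_block),
              seed = as.integer(seed),
              road_length_params = road_length_params,
              p_no_road = p_no_road,
              covariate_spatial_range = covariate_spatial_range,
              covariate_nugget = covariate_nugget,
              overdispersion_sd = overdispersion_sd,
              true_effects = true_effects,
              true_beta = true_beta,
              spatial_amplitude = spatial_amplitude,
              spacetime_amplitude = spacetime_amplitude,
              browsing_params = browsing_params,
              browsing_spatial_range = browsing_spatial_range,
              browsing_nugget_sd = browsing_nugget_sd,
              browsing_drop_fraction = browsing_drop_fraction,
              saplings_per_district = as.integer(saplings_per_district),
              harvest_params = harvest_params)
  class(cfg) <- "dvc_config"
  validate_config(cfg)
  cfg
}

#' @rdname landscape_config
#' @export
default_road_lengths <- function() {
  data.frame(road_type = road_types(),
             meanlog = c(log(5), log(5), log(6), log(7), log(20)),
             sdlog = c(0.5, 0.6, 0.6, 0.6, 0.5))
}

#' @rdname landscape_config
#' @export
default_true_effects <- function() {
  data.frame(
    covariate = c("bio6", "bio11", "bio18", "forest_edge", "urban",
                  "oak_fir"),
    fun = c("monotone", "sin", "quadratic", "quadratic", "linear",
            "monotone"),
    amplitude = c(0.6, 0.6, 0.6, 0.4, -0.4, 0.4))
}

#' @rdname landscape_config
#' @export
default_true_beta <- function() {
  c(intercept = log(0.08),
    road_motorway = -2, road_primary = 1, road_secondary = 1.6,
    road_tertiary = 1.3,
    year2009 = log(1.15),
    `road_motorway:year2009` = -0.15, `road_primary:year2009` = 0.05,
    `road_secondary:year2009` = 0.08, `road_tertiary:year2009` = 0.06,
    red_deer = log(0.76))
}

#' @rdname landscape_config
#' @export
default_browsing_params <- function() {
  data.frame(class = browsing_classes(),
             base_logit = c(-2.2, -0.8, -0.4, -1.4),
             amplitude = c(0.8, 0.8, 0.8, 0.8))
}

validate_config <- function(cfg) {
  if (cfg$grid_rows < 2L || cfg$grid_cols < 2L)
    stop_config("grid dimensions must be >= 2")
  if (cfg$district_block < 1L)
    stop_config("district_block must be positive")
  if (cfg$grid_rows %% cfg$district_block != 0L ||
      cfg$grid_cols %% cfg$district_block != 0L)
    stop_config("district_block must divide both grid dimensions")
  rl <- cfg$road_length_params
  if (!all(c("road_type", "meanlog", "sdlog") %in% names(rl)) ||
      !setequal(rl$road_type, road_types()))
    stop_config("road_length_params must cover the five road types")
  if (any(rl$sdlog <= 0)) stop_config("road length sdlog must be > 0")
  p <- cfg$p_no_road
  if (!all(road_types() %in% names(p)))
    stop_config("p_no_road must be named by road type")
  if (any(p < 0 | p >= 1)) stop_config("p_no_road must lie in [0, 1)")
  if (cfg$covariate_spatial_range <= 0)
    stop_config("covariate_spatial_range must be > 0")
  if (cfg$covariate_nugget < 0 || cfg$covariate_nugget > 1)
    stop_config("covariate_nugget must lie in [0, 1]")
  if (cfg$overdispersion_sd < 0)
    stop_config("overdispersion_sd must be >= 0")
  te <- cfg$true_effects
  if (nrow(te) > 0) {
    if (!all(c("covariate", "fun", "amplitude") %in% names(te)))
      stop_config("true_effects needs covariate/fun/amplitude columns")
    bad <- setdiff(te$covariate,
                   c(climate_vars(), landuse_vars(), browsing_classes()))
    if (length(bad))
      stop_config("unknown covariate in true_effects: ",
                  paste(bad, collapse = ", "))
    badf <- setdiff(te$fun, c("sin", "quadratic", "monotone", "linear"))
    if (length(badf))
      stop_config("unknown effect function tag: ",
                  paste(badf, collapse = ", "))
  }
  if (length(cfg$true_beta) != 11L ||
      !all(names(default_true_beta()) %in% names(cfg$true_beta)))
    stop_config("true_beta must contain the 11 named stage-1 coefficients")
  bp <- cfg$browsing_params
  if (!setequal(bp$class, browsing_classes()))
    stop_config("browsing_params must cover the four palatability classes")
  bd <- cfg$browsing_drop_fraction
  if (any(bd < 0 | bd > 1))
    stop_config("browsing_drop_fraction must lie in [0, 1]")
  if (length(bd) > 1 && !all(browsing_classes() %in% names(bd)))
    stop_config("per-class browsing_drop_fraction must be named by class")
  if (cfg$saplings_per_district < 1L)
    stop_config("saplings_per_district must be positive")
  if (cfg$browsing_nugget_sd < 0)
    stop_config("browsing_nugget_sd must be >= 0")
  invisible(cfg)
}

#' @export
print.dvc_config <- function(x, ...) {
  cat("Synthetic landscape configuration\n")
  cat(sprintf("  grid: %d x %d municipalities, %d x %d district blocks\n",
              x$grid_rows, x$grid_cols, x$district_block, x$district_block))
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  true effects: %d of %d covariates\n",
              nrow(x$true_effects),
              length(c(climate_vars(), landuse_vars(), browsing_classes()))))
  cat(sprintf("  overdispersion sd: %.3g, spatial amplitude: %.3g\n",
              x$overdispersion_sd, x$spatial_amplitude))
  invisible(x)
}
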