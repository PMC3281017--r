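#' @keywords internal
"_PACKAGE"

## Canonical level sets used throughout the package ------------------------

#' Road categories, survey years, covariate names
#'
#' The five public road categories, the two survey years and the fixed
#' covariate vocabulary (9 bioclimatic variables, 10 land-use variables
#' including forest-edge length, 4 browsing palatability classes) used by
#' the generators and models.
#'
#' @return Character (or integer, for years) vector of levels.
#' @export
road_types <- function() {
  c("motorway", "primary", "secondary", "tertiary", "residential")
}

#' @rdname road_types
#' @export
survey_years <- function() c(2006L, 2009L)

#' @rdname road_types
#' @export
climate_vars <- function() {
  c("bio1", "bio4", "bio6", "bio7", "bio10", "bio11", "bio12", "bio18",
    "bio19")
}

#' @rdname road_types
#' @export
landuse_vars <- function() {
  c("meadows", "swamps", "industry", "urban", "complex_habitats",
    "conifer_forest", "mixed_forest", "broadleaf_forest", "arable",
    "forest_edge")
}

#' @rdname road_types
#' @export
browsing_classes <- function() {
  c("spruce_pine", "oak_fir", "ash_maple_elm_linden", "beech_other")
}

## Error helpers ------------------------------------------------------------

stop_config <- function(...) {
  stop(structure(class = c("dvc_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("dvc_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("dvc_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

## Seed streams -------------------------------------------------------------

## One user-facing seed; independent substreams for the different random
## components so that e.g. regenerating the browsing survey does not shift
## the collision draws.
.streams <- c(landscape = 0L, collisions = 1L, browsing = 2L, harvest = 3L,
              oob = 4L, stability = 5L, kmeans = 6L, pipeline = 7L)

stream_seed <- function(seed, stream) {
  stopifnot(stream %in% names(.streams))
  (abs(as.integer(seed)) %% 268435441L) * 8L + .streams[[stream]]
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Polynomial rolling hash of a canonical character representation; used to
## stamp pipeline outputs with their configuration.
dvc_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
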