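## Simulate the sapling browsing survey on the district graph and the
## district harvest table used for external validation.

#' Simulate a sapling browsing survey
#'
#' Per district and palatability class, draws
#' \code{n_browsed ~ Binomial(n_examined, plogis(truth))} where the truth
#' logit is the district-level field stored on the graph (baseline class
#' logit plus a smooth spatial field). A configurable fraction of
#' district x class cells is dropped, emulating genera absent from some
#' districts.
#'
#' @param graph district graph from \code{\link{generate_landscape}} (must
#'   carry the \code{browsing_truth} logit matrix).
#' @param config the \code{\link{landscape_config}}.
#' @return Sapling survey table (\code{district_id},
#'   \code{palatability_class}, \code{n_examined}, \code{n_browsed}) with
#'   the true logit matrix attached as attribute \code{"truth"}.
#' @export
simulate_browsing_survey <- function(graph, config) {
  validate_config(config)
  truth <- graph$browsing_truth
  if (is.null(truth))
    stop_config("graph carries no browsing truth; use generate_landscape()")
  if (!identical(rownames(truth), graph$nodes))
    stop_config("browsing truth does not match graph nodes")
  D <- length(graph$nodes)
  out <- expand.grid(district_id = graph$nodes,
                     palatability_class = browsing_classes(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_examined <- config$saplings_per_district
  drop_frac <- config$browsing_drop_fraction
  drop_frac <- if (length(drop_frac) > 1)
    drop_frac[out$palatability_class] else rep(drop_frac, nrow(out))
  with_seed(stream_seed(config$seed, "browsing"), {
    p <- stats::plogis(truth[cbind(out$district_id,
                                   out$palatability_class)])
    out$n_browsed <- stats::rbinom(nrow(out), out$n_examined, p)
    keep <- stats::runif(nrow(out)) >= drop_frac
  })
  out <- out[keep, ]
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Simulate district harvest densities
#'
#' District harvest per 100 ha is a saturating monotone transform of the
#' district-mean true DVC index, \code{hmax * I / (half_sat + I)}, times
#' mean-one lognormal noise. The saturating form rises roughly linearly
#' for small indices and plateaus for high ones.
#'
#' @param munis municipality table.
#' @param index_truth positive per-municipality index, named by
#'   \code{muni_id} or aligned with \code{munis} rows (e.g.
#'   \code{\link{true_dvc_index}}).
#' @param config the \code{\link{landscape_config}} (uses
#'   \code{harvest_params} and the harvest seed substream).
#' @return Data frame (\code{district_id}, \code{harvest_per_100ha}).
#' @export
simulate_harvest <- function(munis, index_truth, config) {
  validate_config(config)
  if (!is.null(names(index_truth)))
    index_truth <- index_truth[munis$muni_id]
  if (length(index_truth) != nrow(munis) || any(!is.finite(index_truth)) ||
      any(index_truth <= 0))
    stop_validation("index_truth must be positive, one value per municipality")
  dmean <- tapply(index_truth, munis$district_id, mean)
  hp <- config$harvest_params
  h <- hp$hmax * dmean / (hp$half_sat + dmean)
  with_seed(stream_seed(config$seed, "harvest"), {
    noise <- stats::rlnorm(length(h), -hp$noise_sd^2 / 2, hp$noise_sd)
  })
  data.frame(district_id = names(dmean),
             harvest_per_100ha = as.numeric(h * noise))
}
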