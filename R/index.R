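## The DVC index: exp of the summed nonparametric contributions per
## municipality, its multiplicative decomposition into term groups, and
## k-means risk classification.

index_groups <- function() {
  c("climate", "landuse", "browsing", "space", "spacetime",
    "overdispersion")
}

## Per-municipality, per-learner raw (uncentered) contributions for a year.
learner_contributions <- function(fit, munis, year, learners = NULL) {
  nm <- vapply(fit$learners, `[[`, "", "name")
  keep <- if (is.null(learners)) nm else intersect(nm, learners)
  kinds <- vapply(fit$learners, `[[`, "", "kind")
  nd <- munis
  nd$year <- as.integer(year)
  miss <- setdiff(unlist(lapply(fit$learners[match(keep, nm)], function(s)
    switch(s$kind, pspline = , mono_pspline = s$covariate,
           linear = s$covariates, random_intercept = NULL,
           c(s$xvar, s$yvar)))),
    names(nd))
  if (length(miss))
    stop_validation("municipality table lacks selected covariates: ",
                    paste(miss, collapse = ", "))
  out <- matrix(0, nrow(munis), length(keep),
                dimnames = list(munis$muni_id, keep))
  for (l in keep) {
    j <- match(l, nm)
    if (kinds[j] == "random_intercept") next  # observation-level, not mapped
    out[, l] <- bl_predict(fit$designs[[j]], fit$coefficients[[j]], nd)
  }
  out
}

#' Compute the DVC index
#'
#' The DVC index of a municipality is the exponentiated sum of the
#' nonparametric model contributions: the multiplicative change in
#' expected collisions per kilometer relative to the stage-1 parametric
#' baseline. An index of 0.5 halves, an index of 2 doubles the baseline
#' expectation. By default only the structural 2006-type terms (climate,
#' land use, browsing, spatial surface) enter the mapped index; the
#' 2009-only spatio-temporal surface and the observation-level
#' overdispersion intercepts are toggles.
#'
#' @param fit a \code{\link{fit_boost}} result.
#' @param munis municipality table with all selected covariates.
#' @param year index year (2006 or 2009; the spatio-temporal surface can
#'   only contribute in its active year).
#' @param selected optional character vector of learner names surviving
#'   stability selection; \code{NULL} uses all learners.
#' @param include_spacetime include the spatio-temporal factor in the
#'   index product (default \code{FALSE}).
#' @param include_overdispersion include the overdispersion factor in the
#'   index product (always 1 at municipality level, where no
#'   observation intercepts exist; default \code{FALSE}).
#' @return Data frame of class \code{"dvc_index"}: \code{muni_id},
#'   \code{year}, \code{index} and one positive factor column per term
#'   group. The included group factors multiply to the index.
#' @export
compute_index <- function(fit, munis, year = 2006L, selected = NULL,
                          include_spacetime = FALSE,
                          include_overdispersion = FALSE) {
  dec <- decompose_index(fit, munis, year, selected = selected)
  groups <- c("climate", "landuse", "browsing", "space",
              if (include_spacetime) "spacetime",
              if (include_overdispersion) "overdispersion")
  idx <- apply(dec[, intersect(groups, names(dec)), drop = FALSE], 1, prod)
  out <- cbind(data.frame(muni_id = dec$muni_id, year = as.integer(year),
                          index = as.numeric(idx)),
               dec[, setdiff(names(dec), c("muni_id", "year")),
                   drop = FALSE])
  class(out) <- c("dvc_index", "data.frame")
  attr(out, "included_groups") <- groups
  attr(out, "group_log_sd") <- attr(dec, "group_log_sd")
  out
}

#' Multiplicative decomposition of the DVC index
#'
#' Per-group factor = exp of the summed contributions of that group's
#' learners; the variability (standard deviation of the log factors across
#' municipalities) summarizes each group's importance.
#'
#' @inheritParams compute_index
#' @param grouping optional named character vector mapping learner name to
#'   group; defaults to the groups declared on the learner specs.
#' @return Data frame with \code{muni_id} and one factor column per group;
#'   the per-group log-scale standard deviations are attached as attribute
#'   \code{"group_log_sd"}.
#' @export
decompose_index <- function(fit, munis, year = 2006L, selected = NULL,
                            grouping = NULL) {
  nm <- vapply(fit$learners, `[[`, "", "name")
  if (is.null(grouping))
    grouping <- stats::setNames(vapply(fit$learners, `[[`, "", "group"), nm)
  nogrp <- setdiff(nm, names(grouping))
  if (length(nogrp))
    stop_config("learners without a group: ", paste(nogrp, collapse = ", "))
  bad <- setdiff(unique(grouping), index_groups())
  if (length(bad))
    stop_config("unknown groups: ", paste(bad, collapse = ", "))
  contrib <- learner_contributions(fit, munis, year, learners = selected)
  out <- data.frame(muni_id = munis$muni_id)
  log_sd <- stats::setNames(numeric(length(index_groups())), index_groups())
  for (g in index_groups()) {
    members <- intersect(colnames(contrib), names(grouping)[grouping == g])
    lf <- if (length(members))
      rowSums(contrib[, members, drop = FALSE]) else numeric(nrow(munis))
    out[[g]] <- exp(lf)
    log_sd[[g]] <- stats::sd(lf)
  }
  attr(out, "group_log_sd") <- log_sd
  out
}

#' Classify municipalities into risk classes
#'
#' One-dimensional k-means (20 random restarts, deterministic given the
#' seed) on the index values; class labels are renumbered by ascending
#' class mean, so class 1 is the lowest-risk class.
#'
#' @param index a \code{\link{compute_index}} table (or numeric vector).
#' @param k number of classes (default 7).
#' @param seed integer seed for the k-means restarts.
#' @param on_log cluster log-index instead of the raw index scale.
#' @return Object of class \code{"dvc_risk_classes"}: per-municipality
#'   labels, ordered class centers and the class boundaries on the index
#'   scale (midpoints between adjacent classes).
#' @export
classify_risk <- function(index, k = 7L, seed = 1L, on_log = FALSE) {
  x <- if (is.data.frame(index)) index$index else as.numeric(index)
  ids <- if (is.data.frame(index)) index$muni_id else seq_along(x)
  if (k < 2) stop_validation("k must be >= 2")
  if (length(unique(x)) < k)
    stop_validation("k exceeds the number of distinct index values")
  z <- if (on_log) log(x) else x
  km <- with_seed(stream_seed(seed, "kmeans"),
                  stats::kmeans(z, centers = k, nstart = 20L,
                                iter.max = 100L))
  ord <- order(km$centers)
  relabel <- match(seq_len(k), ord)
  cls <- relabel[km$cluster]
  centers <- sort(as.numeric(km$centers))
  if (on_log) centers <- exp(centers)
  hi <- tapply(x, factor(cls, levels = seq_len(k)), max)
  lo <- tapply(x, factor(cls, levels = seq_len(k)), min)
  boundaries <- (hi[-k] + lo[-1]) / 2
  structure(list(classes = data.frame(muni_id = ids, class = cls),
                 centers = centers,
                 boundaries = as.numeric(boundaries),
                 k = as.integer(k)),
            class = "dvc_risk_classes")
}

#' @export
print.dvc_risk_classes <- function(x, ...) {
  cat(sprintf("Risk classification: %d classes, centers %s\n", x$k,
              paste(round(x$centers, 3), collapse = ", ")))
  invisible(x)
}
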