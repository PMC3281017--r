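## External validation: district-mean DVC index vs. harvest density,
## Spearman rank correlation and a robust LOWESS trend.

#' District means of the DVC index
#'
#' Unweighted arithmetic mean of the municipality indices per
#' game-management district (a municipality belongs to the district
#' containing its centroid).
#'
#' @param index a \code{\link{compute_index}} table (or data frame with
#'   \code{muni_id} and \code{index}).
#' @param munis municipality table assigning each municipality a district.
#' @return Data frame (\code{district_id}, \code{mean_index}).
#' @export
aggregate_index_by_district <- function(index, munis) {
  i <- match(index$muni_id, munis$muni_id)
  if (anyNA(i))
    stop_validation("index rows reference unknown municipalities")
  dm <- tapply(index$index, munis$district_id[i], mean)
  empty <- setdiff(unique(munis$district_id), names(dm))
  if (length(empty))
    warning("districts without municipalities omitted: ",
            paste(empty, collapse = ", "))
  data.frame(district_id = names(dm), mean_index = as.numeric(dm))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. The two-sided p-value uses the exact
#' permutation distribution for n <= 8 and the t-approximation with
#' n - 2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with \code{rho}, \code{p_value} and \code{n}.
#' @examples
#' spearman_corr(1:4, c(4, 3, 2, 1))$rho  # -1
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop_validation("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_validation("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_numeric("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p_value <- min(1, 2 * stats::pt(-abs(t_stat), df = n - 2))
  }
  list(rho = rho, p_value = p_value, n = n)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Robust LOWESS trend
#'
#' Locally weighted linear regression with tricube weights and three
#' bisquare robustness iterations (the classical LOWESS), evaluated at the
#' sorted unique abscissae.
#'
#' @param x,y numeric vectors (n >= 5).
#' @param span smoothing span in (0, 1]; each local fit uses
#'   \code{floor(span * n)} neighbours (at least 2).
#' @return Data frame (\code{x}, \code{fitted}) with strictly increasing
#'   \code{x}.
#' @export
lowess_fit <- function(x, y, span = 2 / 3) {
  if (length(x) != length(y)) stop_validation("x and y lengths differ")
  if (length(x) < 5) stop_validation("need at least 5 observations")
  if (span <= 0 || span > 1) stop_validation("span must lie in (0, 1]")
  if (floor(span * length(x)) < 2)
    stop_validation("span too small: local fits need at least 2 points")
  fit <- stats::lowess(x, y, f = span, iter = 3L)
  agg <- tapply(fit$y, fit$x, mean)
  data.frame(x = as.numeric(names(agg)), fitted = as.numeric(agg))
}

#' Validate the DVC index against harvest densities
#'
#' Aggregates the index to districts, joins the harvest table, computes
#' the Spearman rank correlation and fits the LOWESS trend of harvest
#' density on district-mean index.
#'
#' @param index a \code{\link{compute_index}} table.
#' @param munis municipality table.
#' @param harvest data frame (\code{district_id},
#'   \code{harvest_per_100ha}).
#' @param span LOWESS span.
#' @return Object of class \code{"dvc_validation"}: the per-district
#'   table, \code{rho}, \code{p_value} and the fitted curve.
#' @export
validate_against_harvest <- function(index, munis, harvest, span = 2 / 3) {
  dm <- aggregate_index_by_district(index, munis)
  i <- match(dm$district_id, harvest$district_id)
  if (anyNA(i))
    stop_validation("harvest table lacks districts: ",
                    paste(dm$district_id[is.na(i)], collapse = ", "))
  dm$harvest_per_100ha <- harvest$harvest_per_100ha[i]
  sc <- spearman_corr(dm$mean_index, dm$harvest_per_100ha)
  curve <- lowess_fit(dm$mean_index, dm$harvest_per_100ha, span = span)
  structure(list(table = dm, rho = sc$rho, p_value = sc$p_value,
                 curve = curve),
            class = "dvc_validation")
}

#' @export
print.dvc_validation <- function(x, ...) {
  cat(sprintf("Index-harvest validation: %d districts, Spearman rho = %.3f (p = %.3g)\n",
              nrow(x$table), x$rho, x$p_value))
  invisible(x)
}
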