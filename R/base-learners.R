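## Base-learners for component-wise boosting: penalized B-spline smooths
## (optionally monotone), tensor-product spatial and 2009-only
## spatio-temporal surfaces, and observation-level ridge intercepts.
## All smooth learners are calibrated to a common effective degrees of
## freedom (hat-matrix trace), so no learner is favoured in the selection
## step merely for being more flexible.

#' Base-learner specifications
#'
#' Constructors for the building blocks of the stage-2 additive model:
#' \describe{
#'   \item{\code{bl_pspline}}{penalized cubic B-spline of one covariate
#'     with a difference penalty (P-spline).}
#'   \item{\code{bl_mono_pspline}}{as \code{bl_pspline}, but the fitted
#'     coefficient vector is projected onto nondecreasing sequences after
#'     every penalized fit, guaranteeing a nondecreasing partial function
#'     (used for the browsing intensities).}
#'   \item{\code{bl_spatial}}{tensor-product B-spline surface of the
#'     municipality centroid coordinates with a Kronecker-sum first-order
#'     difference penalty.}
#'   \item{\code{bl_spatiotemporal}}{the same surface, but its design rows
#'     are zero except for observations in 2009; captures spatial change
#'     between the survey years.}
#'   \item{\code{bl_random_intercept}}{one ridge-penalized intercept per
#'     training observation; absorbs extra-Poisson variation
#'     (overdispersion) and contributes zero for new observations.}
#' }
#'
#' @param covariate name of the covariate column.
#' @param group term group used by the DVC index decomposition: one of
#'   \code{"climate"}, \code{"landuse"}, \code{"browsing"}, \code{"space"},
#'   \code{"spacetime"}, \code{"overdispersion"}.
#' @param n_knots number of interior knots (univariate smooths).
#' @param degree B-spline degree.
#' @param penalty_order order of the difference penalty.
#' @param target_df effective degrees of freedom every learner is
#'   calibrated to (hat-matrix trace).
#' @param name learner name (defaults to the covariate).
#' @param xvar,yvar centroid coordinate columns (surfaces).
#' @param k_marginal marginal B-spline basis size of the tensor product.
#' @param year_var,active_year year column and the only year for which the
#'   spatio-temporal surface may be nonzero.
#' @return An object of class \code{"bl_spec"}.
#' @export
bl_pspline <- function(covariate, group, n_knots = 20L, degree = 3L,
                       penalty_order = 2L, target_df = 4,
                       name = covariate) {
  new_bl_spec(name = name, kind = "pspline", covariate = covariate,
              group = group, n_knots = n_knots, degree = degree,
              penalty_order = penalty_order, target_df = target_df)
}

#' @rdname bl_pspline
#' @export
bl_mono_pspline <- function(covariate, group = "browsing", n_knots = 20L,
                            degree = 3L, penalty_order = 2L, target_df = 4,
                            name = covariate) {
  new_bl_spec(name = name, kind = "mono_pspline", covariate = covariate,
              group = group, n_knots = n_knots, degree = degree,
              penalty_order = penalty_order, target_df = target_df)
}

#' @rdname bl_pspline
#' @export
bl_spatial <- function(xvar = "centroid_x", yvar = "centroid_y",
                       k_marginal = 8L, degree = 3L, penalty_order = 1L,
                       target_df = 4, name = "f_spatial",
                       group = "space") {
  new_bl_spec(name = name, kind = "spatial", xvar = xvar, yvar = yvar,
              k_marginal = k_marginal, degree = degree,
              penalty_order = penalty_order, target_df = target_df,
              group = group)
}

#' @rdname bl_pspline
#' @export
bl_spatiotemporal <- function(xvar = "centroid_x", yvar = "centroid_y",
                              k_marginal = 8L, degree = 3L,
                              penalty_order = 1L, target_df = 4,
                              year_var = "year", active_year = 2009L,
                              name = "f_spacetime", group = "spacetime") {
  new_bl_spec(name = name, kind = "spatiotemporal", xvar = xvar,
              yvar = yvar, k_marginal = k_marginal, degree = degree,
              penalty_order = penalty_order, target_df = target_df,
              year_var = year_var, active_year = as.integer(active_year),
              group = group)
}

#' @rdname bl_pspline
#' @export
bl_random_intercept <- function(target_df = 4, name = "overdispersion",
                                group = "overdispersion") {
  new_bl_spec(name = name, kind = "random_intercept", target_df = target_df,
              group = group)
}

#' @rdname bl_pspline
#' @param covariates character vector of columns entering an unpenalized
#'   linear learner (an intercept is always included); in the
#'   single-learner limit boosting with such a learner converges to the
#'   corresponding offset-GLM maximum likelihood fit.
#' @export
bl_linear <- function(covariates, group, target_df = length(covariates) + 1,
                      name = paste(covariates, collapse = "+")) {
  new_bl_spec(name = name, kind = "linear", covariates = covariates,
              group = group, target_df = target_df)
}

new_bl_spec <- function(...) {
  spec <- list(...)
  stopifnot(spec$kind %in% c("pspline", "mono_pspline", "spatial",
                             "spatiotemporal", "random_intercept",
                             "linear"))
  if (spec$target_df <= 0) stop_config("target_df must be positive")
  groups <- c("climate", "landuse", "browsing", "space", "spacetime",
              "overdispersion")
  if (!spec$group %in% groups)
    stop_config("unknown learner group: ", spec$group)
  if (spec$kind == "mono_pspline" && spec$group != "browsing")
    stop_config("monotone smooths are reserved for browsing covariates")
  structure(spec, class = "bl_spec")
}

#' @export
print.bl_spec <- function(x, ...) {
  cat(sprintf("<base-learner %s: %s, group %s, df %.3g>\n",
              x$name, x$kind, x$group, x$target_df))
  invisible(x)
}

#' Default base-learner set
#'
#' One P-spline per climate and land-use covariate, one monotone P-spline
#' per browsing class, the spatial and spatio-temporal surfaces, and the
#' observation-level ridge intercepts: 26 learners in total.
#'
#' @inheritParams bl_pspline
#' @return List of \code{"bl_spec"} objects.
#' @export
default_learners <- function(target_df = 4) {
  c(lapply(climate_vars(), bl_pspline, group = "climate",
           target_df = target_df),
    lapply(landuse_vars(), bl_pspline, group = "landuse",
           target_df = target_df),
    lapply(browsing_classes(), bl_mono_pspline, group = "browsing",
           target_df = target_df),
    list(bl_spatial(target_df = target_df),
         bl_spatiotemporal(target_df = target_df),
         bl_random_intercept(target_df = target_df)))
}

## ---- basis construction --------------------------------------------------

## Equidistant B-spline basis on [a, b] with n_knots interior knots.
pspline_knots <- function(a, b, n_knots, degree) {
  if (b <= a) b <- a + 1e-8
  dx <- (b - a) / (n_knots + 1)
  seq(a - degree * dx, by = dx, length.out = n_knots + 2L * degree + 2L)
}

eval_bspline <- function(x, knots, degree, warn = FALSE) {
  a <- knots[degree + 1]; b <- knots[length(knots) - degree]
  if (any(x < a - 1e-12) || any(x > b + 1e-12)) {
    if (warn)
      warning("values outside the training range; clamped to boundary knots")
    x <- pmin(pmax(x, a), b)
  } else {
    x <- pmin(pmax(x, a), b)
  }
  splines::splineDesign(knots, x, ord = degree + 1, outer.ok = FALSE)
}

diff_penalty <- function(k, order) {
  D <- diff(diag(k), differences = order)
  crossprod(D)
}

## Effective df of the smoother for given lambda: tr((M + lambda P)^-1 M).
hat_trace <- function(M, P, lambda) {
  sum(diag(solve(M + lambda * P, M)))
}

## Find lambda with hat trace equal to target_df by bisection.
calibrate_lambda <- function(M, P, target_df, tol = 1e-6) {
  f <- function(lam) tryCatch(hat_trace(M, P, lam), error = function(e) NA)
  lo <- 0
  df_lo <- f(lo)
  for (eps in 10^seq(-10, -2)) {
    if (!is.na(df_lo)) break
    lo <- eps
    df_lo <- f(lo)
  }
  if (is.na(df_lo)) stop_numeric("singular base-learner design")
  if (df_lo <= target_df + tol) return(lo)
  hi <- 1
  while (f(hi) > target_df && hi < 1e12) hi <- hi * 10
  if (f(hi) > target_df)
    stop_numeric("target_df not attainable: penalty null space too large")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    df_mid <- f(mid)
    if (abs(df_mid - target_df) < tol) return(mid)
    if (df_mid > target_df) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Build a base-learner design
#'
#' Materializes a base-learner on a data set: design matrix, penalty
#' matrix, and the ridge amount calibrated such that the trace of the
#' penalized-least-squares hat matrix equals the learner's target degrees
#' of freedom (bisection, tolerance 1e-6). For the random intercept the
#' calibration has the closed form \code{lambda = n / df - 1}.
#'
#' @param spec a \code{"bl_spec"}.
#' @param data model data frame (covariates, centroid coordinates, year).
#' @return List of class \code{"bl_design"} with elements \code{B}
#'   (design), \code{P} (penalty), \code{lambda}, \code{solver}
#'   (pre-factored penalized least squares), knots and the spec.
#' @export
build_design <- function(spec, data) {
  n <- nrow(data)
  if (spec$kind == "random_intercept") {
    lambda <- n / spec$target_df - 1
    return(structure(list(spec = spec, n = n, lambda = lambda),
                     class = "bl_design"))
  }
  if (spec$kind == "linear") {
    miss <- setdiff(spec$covariates, names(data))
    if (length(miss))
      stop_validation("covariate not found: ", paste(miss, collapse = ", "))
    B <- cbind(1, as.matrix(data[spec$covariates]))
    des <- list(spec = spec, B = B, P = diag(0, ncol(B)), lambda = 0,
                solver = tryCatch(chol(crossprod(B)),
                                  error = function(e)
                                    stop_numeric("singular linear design for ",
                                                 spec$name)),
                n = n)
    return(structure(des, class = "bl_design"))
  }
  if (spec$kind %in% c("pspline", "mono_pspline")) {
    x <- data[[spec$covariate]]
    if (is.null(x)) stop_validation("covariate not found: ", spec$covariate)
    if (length(unique(x)) < spec$degree + 2L)
      stop_validation("too few distinct values for a spline in ",
                      spec$covariate)
    knots <- pspline_knots(min(x), max(x), spec$n_knots, spec$degree)
    B <- eval_bspline(x, knots, spec$degree)
    P <- diff_penalty(ncol(B), spec$penalty_order)
    des <- list(spec = spec, B = B, P = P, knots = knots)
  } else {
    x <- data[[spec$xvar]]; y <- data[[spec$yvar]]
    kx <- pspline_knots(min(x), max(x),
                        spec$k_marginal - spec$degree - 1L, spec$degree)
    ky <- pspline_knots(min(y), max(y),
                        spec$k_marginal - spec$degree - 1L, spec$degree)
    Bx <- eval_bspline(x, kx, spec$degree)
    By <- eval_bspline(y, ky, spec$degree)
    B <- tensor_rows(Bx, By)
    Px <- diff_penalty(ncol(Bx), spec$penalty_order)
    Py <- diff_penalty(ncol(By), spec$penalty_order)
    P <- kronecker(Px, diag(ncol(By))) + kronecker(diag(ncol(Bx)), Py)
    if (spec$kind == "spatiotemporal") {
      active <- data[[spec$year_var]] == spec$active_year
      B[!active, ] <- 0
    }
    des <- list(spec = spec, B = B, P = P, kx = kx, ky = ky)
  }
  M <- crossprod(des$B)
  des$lambda <- calibrate_lambda(M, des$P, spec$target_df)
  des$solver <- tryCatch(chol(M + des$lambda * des$P),
                         error = function(e)
                           stop_numeric("singular penalized design for ",
                                        spec$name))
  des$n <- n
  structure(des, class = "bl_design")
}

tensor_rows <- function(A, B) {
  ## row-wise Kronecker product
  out <- matrix(0, nrow(A), ncol(A) * ncol(B))
  for (j in seq_len(ncol(A)))
    out[, (j - 1L) * ncol(B) + seq_len(ncol(B))] <- A[, j] * B
  out
}

## Penalized least-squares fit of a base-learner to a working response u.
## Returns coefficients, fitted values, and the penalized residual sum of
## squares used for learner competition.
bl_fit <- function(des, u) {
  spec <- des$spec
  if (spec$kind == "random_intercept") {
    g <- u / (1 + des$lambda)
    crit <- sum((u - g)^2) + des$lambda * sum(g^2)
    return(list(coef = g, fitted = g, crit = crit))
  }
  rhs <- crossprod(des$B, u)
  gamma <- backsolve(des$solver, forwardsolve(t(des$solver), rhs))
  if (spec$kind == "mono_pspline") {
    ## isotonic projection: nondecreasing coefficients give a
    ## nondecreasing B-spline
    gamma <- stats::isoreg(seq_along(gamma), gamma)$yf
  }
  fitted <- drop(des$B %*% gamma)
  crit <- sum((u - fitted)^2) +
    des$lambda * drop(crossprod(gamma, des$P %*% gamma))
  list(coef = as.numeric(gamma), fitted = fitted, crit = crit)
}

## Evaluate a learner's aggregated coefficients on new data (zero for the
## random intercept: it has no structural part).
bl_predict <- function(des, coef, newdata, warn = FALSE) {
  spec <- des$spec
  if (spec$kind == "random_intercept") return(rep(0, nrow(newdata)))
  if (spec$kind == "linear")
    return(drop(cbind(1, as.matrix(newdata[spec$covariates])) %*% coef))
  if (spec$kind %in% c("pspline", "mono_pspline")) {
    B <- eval_bspline(newdata[[spec$covariate]], des$knots, spec$degree,
                      warn = warn)
  } else {
    Bx <- eval_bspline(newdata[[spec$xvar]], des$kx, spec$degree,
                       warn = warn)
    By <- eval_bspline(newdata[[spec$yvar]], des$ky, spec$degree,
                       warn = warn)
    B <- tensor_rows(Bx, By)
    if (spec$kind == "spatiotemporal") {
      active <- newdata[[spec$year_var]] == spec$active_year
      B[!active, ] <- 0
    }
  }
  drop(B %*% coef)
}
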