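## Stage 2: component-wise functional gradient boosting of the additive
## Poisson model on the fixed stage-1 offset. At each iteration every
## base-learner is fitted to the current negative gradient by penalized
## least squares; the learner with the smallest penalized residual sum of
## squares is selected (ties broken by lowest index) and the ensemble is
## updated by a fraction nu of its fit.

#' Assemble the stage-2 model frame
#'
#' Joins the collision rows with the municipality covariates and centroid
#' coordinates; the result is the \code{data} argument of
#' \code{\link{fit_boost}} and friends.
#'
#' @param collisions collision table.
#' @param munis municipality table.
#' @return Data frame with one row per collision-table row.
#' @export
boost_data <- function(collisions, munis) {
  validate_collision_table(collisions)
  i <- match(collisions$muni_id, munis$muni_id)
  if (anyNA(i))
    stop_validation("collision rows reference unknown municipalities")
  covs <- c("centroid_x", "centroid_y", climate_vars(), landuse_vars(),
            browsing_classes())
  covs <- intersect(covs, names(munis))
  cbind(collisions[, c("muni_id", "road_type", "year", "count",
                       "road_length", "red_deer")],
        munis[i, covs, drop = FALSE], row.names = NULL)
}

## Core boosting loop shared by fit_boost, select_mstop_oob and
## stability_select. Optionally tracks the linear predictor of a holdout
## set and records its Poisson risk along a grid of iterations.
boost_engine <- function(designs, y, F0, nu, mstop,
                         holdout = NULL, grid = NULL) {
  nL <- length(designs)
  F <- F0
  coefs <- lapply(designs, function(d) {
    if (d$spec$kind == "random_intercept") numeric(d$n)
    else numeric(ncol(d$B))
  })
  path <- integer(mstop)
  risk <- numeric(mstop)
  watch <- NULL
  if (!is.null(holdout)) {
    Fh <- holdout$F0
    watch <- numeric(length(grid))
    gi <- 1L
    if (length(grid) && grid[1] == 0L) {
      watch[1] <- pois_risk(holdout$y, Fh)
      gi <- 2L
    }
  }
  fits <- vector("list", nL)
  for (m in seq_len(mstop)) {
    mu <- exp(F)
    if (any(!is.finite(mu)))
      stop_numeric("diverging linear predictor (overflow); reduce nu")
    u <- y - mu
    best <- 0L; best_crit <- Inf
    for (j in seq_len(nL)) {
      fj <- bl_fit(designs[[j]], u)
      if (fj$crit < best_crit) {
        best <- j; best_crit <- fj$crit; fits[[1L]] <- fj
      }
    }
    fb <- fits[[1L]]
    F <- F + nu * fb$fitted
    coefs[[best]] <- coefs[[best]] + nu * fb$coef
    path[m] <- best
    risk[m] <- pois_risk(y, F)
    if (!is.null(holdout)) {
      Fh <- Fh + nu * holdout$pred(best, fb$coef)
      if (gi <= length(grid) && m == grid[gi]) {
        watch[gi] <- pois_risk(holdout$y, Fh)
        gi <- gi + 1L
      }
    }
  }
  list(coefs = coefs, path = path, F = F, risk = risk, watch = watch)
}

## Mean negative Poisson log-likelihood (up to the y! term).
pois_risk <- function(y, eta) mean(exp(eta) - y * eta)

#' Fit the boosted additive Poisson model
#'
#' Functional gradient boosting: the linear predictor is initialized at
#' the fixed offset; each iteration fits all base-learners to the negative
#' gradient \code{y - exp(F)} by penalized least squares, selects the one
#' with minimal penalized residual sum of squares and adds \code{nu} times
#' its fit. Monotone learners project their coefficients onto
#' nondecreasing sequences after every fit, so each aggregated monotone
#' partial function is nondecreasing.
#'
#' @param data model frame from \code{\link{boost_data}} (needs a
#'   \code{count} column and the learners' covariates).
#' @param offset fixed per-row offset on the log scale, typically
#'   \code{\link{stage1_offset}}.
#' @param learners list of \code{"bl_spec"} objects.
#' @param nu step length in (0, 1].
#' @param mstop number of boosting iterations (>= 0).
#' @return Object of class \code{"dvc_boost"} with aggregated coefficients
#'   per learner, the selection path, in-sample risk path, training linear
#'   predictor, per-learner centering constants and the global centering
#'   intercept.
#' @seealso \code{\link{select_mstop_oob}}, \code{\link{stability_select}},
#'   \code{\link{predict_partial}}
#' @export
fit_boost <- function(data, offset, learners = default_learners(),
                      nu = 0.1, mstop = 100L) {
  stopifnot(nu > 0, nu <= 1, mstop >= 0)
  if (length(offset) != nrow(data))
    stop_validation("offset length must match the data")
  designs <- lapply(learners, build_design, data = data)
  eng <- boost_engine(designs, y = data$count, F0 = offset, nu = nu,
                      mstop = as.integer(mstop))
  names(eng$coefs) <- vapply(learners, `[[`, "", "name")
  contrib <- vapply(seq_along(designs), function(j) {
    d <- designs[[j]]
    if (d$spec$kind == "random_intercept") eng$coefs[[j]]
    else drop(d$B %*% eng$coefs[[j]])
  }, numeric(nrow(data)))
  centering <- colMeans(contrib)
  names(centering) <- names(eng$coefs)
  structure(list(learners = learners, designs = designs,
                 coefficients = eng$coefs,
                 selection_path = eng$path,
                 risk_path = eng$risk,
                 nu = nu, mstop = as.integer(mstop),
                 offset = offset, F = eng$F,
                 centering = centering,
                 intercept = sum(centering),
                 data = data),
            class = "dvc_boost")
}

#' @export
print.dvc_boost <- function(x, ...) {
  sel <- selected_learners(x)
  cat(sprintf("Boosted additive Poisson model: %d learners, nu = %g, mstop = %d\n",
              length(x$learners), x$nu, x$mstop))
  cat(sprintf("  learners ever selected: %d (%s)\n", length(sel),
              paste(utils::head(sel, 8), collapse = ", ")))
  invisible(x)
}

#' Names of learners selected at least once
#' @param fit a \code{"dvc_boost"} object.
#' @export
selected_learners <- function(fit) {
  nm <- vapply(fit$learners, `[[`, "", "name")
  nm[sort(unique(fit$selection_path))]
}

#' Predict from a boosted fit
#'
#' For new data only the structural terms contribute (the observation
#' ridge intercepts are training-row specific and predict zero); for
#' \code{newdata = NULL} the stored training linear predictor (including
#' the intercepts) is returned.
#'
#' @param object a \code{"dvc_boost"} fit.
#' @param newdata optional model frame.
#' @param offset offset for the new rows (required with \code{newdata}).
#' @param type \code{"link"} (log scale) or \code{"response"} (expected
#'   counts).
#' @param ... unused.
#' @export
predict.dvc_boost <- function(object, newdata = NULL, offset = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$F
  } else {
    if (is.null(offset))
      stop_validation("offset required when predicting for new data")
    eta <- offset
    for (j in seq_along(object$designs))
      eta <- eta + bl_predict(object$designs[[j]], object$coefficients[[j]],
                              newdata)
  }
  if (type == "response") exp(eta) else eta
}

#' Partial contribution of one base-learner
#'
#' Evaluates a learner's aggregated coefficients at supplied covariate
#' values, minus its training-mean centering constant, and additionally on
#' the multiplicative (exp) scale: the relative change in expected
#' collisions per km attributable to that term, all else equal. Values
#' outside the training range are clamped to the boundary knots with a
#' warning.
#'
#' @param fit a \code{"dvc_boost"} fit.
#' @param learner learner name.
#' @param values numeric vector (univariate smooths) or data frame with
#'   the learner's input columns (surfaces).
#' @param center subtract the training-mean centering constant
#'   (default TRUE).
#' @return Data frame with the inputs, the centered contribution on the
#'   linear-predictor scale (\code{link}) and its exp
#'   (\code{multiplicative}).
#' @export
predict_partial <- function(fit, learner, values, center = TRUE) {
  nm <- vapply(fit$learners, `[[`, "", "name")
  j <- match(learner, nm)
  if (is.na(j)) stop_validation("unknown learner: ", learner)
  des <- fit$designs[[j]]
  if (des$spec$kind %in% c("pspline", "mono_pspline")) {
    nd <- data.frame(values)
    names(nd) <- des$spec$covariate
  } else if (des$spec$kind == "random_intercept") {
    stop_validation("the observation intercepts have no partial function; ",
                    "use overdispersion_factors()")
  } else {
    nd <- as.data.frame(values)
  }
  link <- bl_predict(des, fit$coefficients[[j]], nd, warn = TRUE)
  if (center) link <- link - fit$centering[[j]]
  out <- cbind(nd, link = link, multiplicative = exp(link))
  rownames(out) <- NULL
  out
}

#' Per-row overdispersion factors of a boosted fit
#'
#' \code{exp} of the aggregated observation-level ridge intercepts for the
#' training rows (1 when no such learner is present or selected).
#'
#' @param fit a \code{"dvc_boost"} fit.
#' @export
overdispersion_factors <- function(fit) {
  kinds <- vapply(fit$learners, `[[`, "", "kind")
  j <- which(kinds == "random_intercept")
  if (!length(j)) return(rep(1, nrow(fit$data)))
  exp(fit$coefficients[[j[1]]])
}

#' Choose the number of boosting iterations by out-of-bootstrap risk
#'
#' For each bootstrap resample (rows drawn with replacement) the model is
#' refitted and the mean negative Poisson log-likelihood on the
#' out-of-bootstrap rows is recorded along a grid of iteration numbers;
#' the grid point minimizing the mean out-of-bootstrap risk is selected.
#'
#' @inheritParams fit_boost
#' @param grid increasing integer grid of candidate iteration numbers.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed (the procedure is deterministic given it).
#' @return Object of class \code{"dvc_oob"}: the replicate x grid risk
#'   matrix, the grid and \code{mstop} (the minimizer of the column mean).
#' @export
select_mstop_oob <- function(data, offset, learners = default_learners(),
                             nu = 0.1, grid = seq(0L, 1500L, by = 25L),
                             n_boot = 25L, seed = 1L) {
  stopifnot(n_boot >= 2, !is.unsorted(grid), all(grid >= 0))
  grid <- as.integer(grid)
  n <- nrow(data)
  risk <- matrix(NA_real_, n_boot, length(grid))
  with_seed(stream_seed(seed, "oob"), {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (!length(oob)) {
        warning("bootstrap replicate with empty out-of-bootstrap set; skipped")
        next
      }
      din <- data[idx, , drop = FALSE]
      dout <- data[oob, , drop = FALSE]
      designs <- lapply(learners, build_design, data = din)
      Bout <- lapply(designs, function(d) {
        if (d$spec$kind == "random_intercept") NULL
        else oob_basis(d, dout)
      })
      holdout <- list(
        y = dout$count, F0 = offset[oob],
        pred = function(j, coef) {
          if (is.null(Bout[[j]])) rep(0, length(oob))
          else drop(Bout[[j]] %*% coef)
        })
      eng <- boost_engine(designs, y = din$count, F0 = offset[idx],
                          nu = nu, mstop = max(grid),
                          holdout = holdout, grid = grid)
      risk[b, ] <- eng$watch
    }
  })
  mean_risk <- colMeans(risk, na.rm = TRUE)
  structure(list(risk = risk, grid = grid, mean_risk = mean_risk,
                 mstop = grid[which.min(mean_risk)]),
            class = "dvc_oob")
}

## Design matrix of a fitted base-learner evaluated at holdout rows.
oob_basis <- function(des, newdata) {
  spec <- des$spec
  if (spec$kind == "linear")
    return(cbind(1, as.matrix(newdata[spec$covariates])))
  if (spec$kind %in% c("pspline", "mono_pspline"))
    return(eval_bspline(newdata[[spec$covariate]], des$knots, spec$degree))
  Bx <- eval_bspline(newdata[[spec$xvar]], des$kx, spec$degree)
  By <- eval_bspline(newdata[[spec$yvar]], des$ky, spec$degree)
  B <- tensor_rows(Bx, By)
  if (spec$kind == "spatiotemporal")
    B[newdata[[spec$year_var]] != spec$active_year, ] <- 0
  B
}

#' @export
print.dvc_oob <- function(x, ...) {
  cat(sprintf("Out-of-bootstrap selection: mstop = %d (grid %d..%d, %d replicates)\n",
              x$mstop, min(x$grid), max(x$grid), nrow(x$risk)))
  invisible(x)
}

#' Stability selection over municipality subsamples
#'
#' Repeatedly fits \code{m_iter} boosting iterations on half-samples of
#' the municipalities (without replacement, all rows of the sampled
#' municipalities) and records, per base-learner, the fraction of
#' replicates in which it was selected in at least one iteration. Learners
#' with frequency above the threshold form the stable set.
#'
#' @inheritParams fit_boost
#' @param m_iter iterations per subsample fit (typically the
#'   out-of-bootstrap selected mstop).
#' @param n_subsamples number of half-samples (>= 2).
#' @param threshold selection-frequency threshold in (0, 1].
#' @param seed integer seed.
#' @return Object of class \code{"dvc_stabsel"}: named selection
#'   frequencies, the threshold and the selected learner names.
#' @export
stability_select <- function(data, offset, learners = default_learners(),
                             nu = 0.1, m_iter = 100L, n_subsamples = 50L,
                             threshold = 0.5, seed = 1L) {
  if (threshold <= 0 || threshold > 1)
    stop_validation("threshold must lie in (0, 1]")
  stopifnot(n_subsamples >= 2)
  nm <- vapply(learners, `[[`, "", "name")
  counts <- stats::setNames(numeric(length(nm)), nm)
  munis <- unique(data$muni_id)
  half <- floor(length(munis) / 2)
  with_seed(stream_seed(seed, "stability"), {
    for (s in seq_len(n_subsamples)) {
      sub <- sample(munis, half)
      rows <- data$muni_id %in% sub
      din <- data[rows, , drop = FALSE]
      if (m_iter < 1L || nu == 0) next
      designs <- lapply(learners, build_design, data = din)
      eng <- boost_engine(designs, y = din$count, F0 = offset[rows],
                          nu = nu, mstop = as.integer(m_iter))
      counts[unique(eng$path)] <- counts[unique(eng$path)] + 1
    }
  })
  freq <- counts / n_subsamples
  structure(list(frequency = freq, n_subsamples = as.integer(n_subsamples),
                 threshold = threshold,
                 selected = names(freq)[freq > threshold]),
            class = "dvc_stabsel")
}

#' @export
print.dvc_stabsel <- function(x, ...) {
  cat(sprintf("Stability selection (%d subsamples, threshold %.2f)\n",
              x$n_subsamples, x$threshold))
  cat("  selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
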