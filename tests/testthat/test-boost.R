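test_that("an empty ensemble reproduces the stage-1 means exactly", {
  w <- small_world()
  fit0 <- fit_boost(w$data, w$off, mstop = 0L)
  expect_identical(predict(fit0, type = "response"), exp(w$off))
  expect_identical(fit0$selection_path, integer(0))
})

test_that("training predictor reconstructs from the aggregated learners", {
  fit <- small_boost()
  recon <- fit$offset
  for (j in seq_along(fit$designs)) {
    d <- fit$designs[[j]]
    recon <- recon + if (d$spec$kind == "random_intercept")
      fit$coefficients[[j]] else drop(d$B %*% fit$coefficients[[j]])
  }
  expect_lt(max(abs(predict(fit) - recon)), 1e-10)
  ## centering constants are the training means of the contributions
  expect_equal(sum(fit$centering), fit$intercept, tolerance = 1e-12)
})

test_that("in-sample risk is non-increasing along the path", {
  fit <- small_boost()
  expect_equal(length(fit$selection_path), fit$mstop)
  expect_true(all(diff(fit$risk_path) <= 1e-10))
})

test_that("partial functions: unselected terms are null, monotone terms nondecreasing", {
  fit <- small_boost()
  nm <- vapply(fit$learners, `[[`, "", "name")
  never <- setdiff(nm[vapply(fit$learners, `[[`, "", "kind") == "pspline"],
                   selected_learners(fit))
  if (length(never)) {
    pp <- predict_partial(fit, never[1], seq(0.1, 0.9, length.out = 50))
    expect_true(all(pp$link == 0))
    expect_true(all(pp$multiplicative == 1))
  }
  for (cl in browsing_classes()) {
    r <- range(fit$data[[cl]])
    pp <- predict_partial(fit, cl, seq(r[1], r[2], length.out = 1000))
    expect_true(all(diff(pp$link) >= -1e-12), label = cl)
  }
  ## extrapolation clamps to the boundary with a warning
  expect_warning(predict_partial(fit, "bio11", c(-5, 5)), "clamp")
})

test_that("single-learner boosting converges to the offset GLM oracle", {
  set.seed(3)
  n <- 150
  d <- data.frame(muni_id = sprintf("m%03d", seq_len(n)),
                  road_type = "residential", year = 2006L,
                  road_length = exp(rnorm(n, 1, 0.3)),
                  red_deer = rep(c(TRUE, FALSE), length.out = n))
  d$count <- rpois(n, d$road_length * exp(-1 + log(0.7) * d$red_deer))
  glm_fit <- fit_offset_glm(d)
  d$red <- as.numeric(d$red_deer)
  bf <- fit_boost(d, log(d$road_length),
                  list(bl_linear("red", group = "climate")),
                  nu = 0.1, mstop = 3000L)
  expect_equal(unname(bf$coefficients[[1]]),
               unname(c(coef(glm_fit)[["(Intercept)"]],
                        coef(glm_fit)[["red_deer"]])),
               tolerance = 1e-5)
})

test_that("boosting inputs are validated", {
  w <- small_world()
  expect_error(fit_boost(w$data, w$off[-1], mstop = 1L), "offset length")
  expect_error(fit_boost(w$data, w$off, nu = 0, mstop = 1L))
})

test_that("out-of-bootstrap selection is deterministic and well-formed", {
  w <- small_world()
  grid <- seq(0L, 50L, by = 10L)
  a <- select_mstop_oob(w$data, w$off, grid = grid, n_boot = 3L, seed = 5L)
  b <- select_mstop_oob(w$data, w$off, grid = grid, n_boot = 3L, seed = 5L)
  expect_identical(a$risk, b$risk)
  expect_equal(a$mstop, a$grid[which.min(colMeans(a$risk))])
  expect_true(all(is.finite(a$risk)))
})

test_that("stability selection: trivial cases and frequency splitting", {
  w <- small_world()
  st0 <- stability_select(w$data, w$off, m_iter = 0L, n_subsamples = 4L,
                          seed = 2L)
  expect_true(all(st0$frequency == 0))
  expect_length(st0$selected, 0L)
  expect_error(stability_select(w$data, w$off, threshold = 1.5), "threshold")

  ## a duplicated learner splits frequency with the original; combined
  ## frequency does not drop below the original alone (documented
  ## correlated-learner caveat)
  base <- list(bl_pspline("bio6", group = "climate"),
               bl_pspline("meadows", group = "landuse"),
               bl_random_intercept())
  st1 <- stability_select(w$data, w$off, base, m_iter = 30L,
                          n_subsamples = 10L, seed = 3L)
  dup <- c(base, list(bl_pspline("bio6", group = "climate",
                                 name = "bio6_dup")))
  st2 <- stability_select(w$data, w$off, dup, m_iter = 30L,
                          n_subsamples = 10L, seed = 3L)
  combined <- st2$frequency[["bio6"]] + st2$frequency[["bio6_dup"]]
  expect_gte(combined, st1$frequency[["bio6"]] - 0.1)
})
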