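test_that("district aggregation is an unweighted group mean", {
  munis <- data.frame(muni_id = c("a", "b", "c"),
                      district_id = c("d1", "d1", "d2"))
  idx <- data.frame(muni_id = c("a", "b", "c"), index = c(1, 3, 5))
  agg <- aggregate_index_by_district(idx, munis)
  expect_equal(agg$mean_index[agg$district_id == "d1"], 2)
  expect_equal(agg$mean_index[agg$district_id == "d2"], 5)

  ## brute-force group-by on a 20-municipality toy
  set.seed(4)
  munis2 <- data.frame(muni_id = sprintf("m%02d", 1:20),
                       district_id = sample(c("x", "y", "z"), 20,
                                            replace = TRUE))
  idx2 <- data.frame(muni_id = munis2$muni_id, index = runif(20, 0.5, 2))
  agg2 <- aggregate_index_by_district(idx2, munis2)
  for (d in unique(munis2$district_id)) {
    manual <- mean(idx2$index[munis2$district_id == d])
    expect_equal(agg2$mean_index[agg2$district_id == d], manual)
  }
})

test_that("spearman: exact values, oracle formula, invariances, errors", {
  expect_equal(spearman_corr(1:3, c(2, 4, 6))$rho, 1)
  expect_equal(spearman_corr(1:4, c(4, 3, 2, 1))$rho, -1)

  ## tie-free 10-point toy vs the classical 1 - 6 sum d^2 / (n(n^2-1))
  set.seed(10)
  x <- sample(1:10); y <- sample(1:10)
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(spearman_corr(x, y)$rho, 1 - 6 * d2 / (10 * 99),
               tolerance = 1e-12)

  ## invariant under strictly monotone transforms of either argument
  u <- runif(15); v <- runif(15)
  base <- spearman_corr(u, v)$rho
  expect_equal(spearman_corr(exp(u), v)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_corr(u, rank(v))$rho, base, tolerance = 1e-12)

  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")

  ## exact permutation p-value for tiny n: perfect agreement of n = 3
  ## occurs in 1 of 6 orderings, two-sided doubles it
  expect_equal(spearman_corr(1:3, 1:3)$p_value, 2 / 6, tolerance = 1e-12)
})

test_that("lowess: line reproduction, constants, validation", {
  x <- 1:20
  lf <- lowess_fit(x, 3 * x - 2)
  expect_equal(lf$fitted, 3 * lf$x - 2, tolerance = 1e-8)
  expect_true(all(diff(lf$x) > 0))
  lc <- lowess_fit(x, rep(5, 20))
  expect_equal(lc$fitted, rep(5, 20), tolerance = 1e-10)
  expect_error(lowess_fit(1:4, 1:4), "at least 5")
  expect_error(lowess_fit(1:20, 1:20, span = 0.05), "span")
})

test_that("harvest validation stage joins, correlates and smooths", {
  w <- study_world()
  truth <- true_dvc_index(w$land$munis, w$cfg)
  idx <- data.frame(muni_id = w$land$munis$muni_id,
                    index = as.numeric(truth))
  harvest <- simulate_harvest(w$land$munis, truth, w$cfg)
  val <- validate_against_harvest(idx, w$land$munis, harvest)
  expect_gt(val$rho, 0)
  expect_lt(val$p_value, 0.05)
  expect_true(all(diff(val$curve$x) > 0))
  expect_error(validate_against_harvest(idx, w$land$munis,
                                        harvest[-1, ]), "lacks")
})
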