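fully_observed_survey <- function() {
  fixture("mrf_survey", function() {
    cfg <- small_config(seed = 21, browsing_drop_fraction = 0)
    land <- generate_landscape(cfg)
    list(cfg = cfg, land = land,
         survey = simulate_browsing_survey(land$graph, cfg))
  })
}

test_that("unpenalized fit reproduces empirical proportions", {
  f <- fully_observed_survey()
  est <- fit_mrf_binomial(f$survey, f$land$graph, lambda = 0)
  for (cl in browsing_classes()) {
    s <- f$survey[f$survey$palatability_class == cl, ]
    emp <- s$n_browsed / s$n_examined
    interior <- emp > 0 & emp < 1
    sm <- est$proportions[s$district_id, cl]
    expect_lt(max(abs(sm[interior] - emp[interior])), 1e-8)
  }
})

test_that("infinite smoothing collapses to the pooled proportion", {
  f <- fully_observed_survey()
  est <- fit_mrf_binomial(f$survey, f$land$graph, lambda = 1e8)
  for (cl in browsing_classes()) {
    s <- f$survey[f$survey$palatability_class == cl, ]
    pooled <- sum(s$n_browsed) / sum(s$n_examined)
    expect_lt(max(abs(est$proportions[, cl] - pooled)), 1e-4)
  }
})

test_that("df calibration and neighbour borrowing for missing districts", {
  f <- fully_observed_survey()
  est <- fit_mrf_binomial(f$survey, f$land$graph, target_df = 6)
  expect_equal(unname(est$edf), rep(6, 4), tolerance = 1e-4)
  expect_true(all(est$proportions > 0 & est$proportions < 1))

  ## drop one district's oak_fir cell: it still receives an estimate,
  ## inside the range of the observed estimates
  s2 <- f$survey
  drop_d <- f$land$graph$nodes[1]
  s2 <- s2[!(s2$district_id == drop_d &
               s2$palatability_class == "oak_fir"), ]
  e2 <- fit_mrf_binomial(s2, f$land$graph, target_df = 6)
  v <- e2$proportions[drop_d, "oak_fir"]
  expect_true(is.finite(v) && v > 0 && v < 1)
})

test_that("a data-free graph component is an error, as are bad counts", {
  graph <- structure(list(nodes = c("a", "b", "c", "d"),
                          edges = data.frame(from = c("a", "c"),
                                             to = c("b", "d"))),
                     class = "district_graph")
  survey <- data.frame(district_id = c("a", "b"),
                       palatability_class = "oak_fir",
                       n_examined = c(75L, 75L), n_browsed = c(10L, 20L))
  expect_error(fit_mrf_binomial(survey, graph, lambda = 1), "component")
  bad <- data.frame(district_id = "a", palatability_class = "oak_fir",
                    n_examined = 10L, n_browsed = 11L)
  expect_error(fit_mrf_binomial(bad, graph, lambda = 1), "n_browsed")
})

test_that("smoothed estimates are monotone in the data at fixed lambda", {
  f <- fully_observed_survey()
  s <- f$survey[f$survey$palatability_class == "beech_other", ]
  target <- s$district_id[3]
  fit_at <- function(extra) {
    s2 <- s
    i <- which(s2$district_id == target)
    s2$n_browsed[i] <- pmin(s2$n_browsed[i] + extra, s2$n_examined[i])
    est <- fit_mrf_binomial(s2, f$land$graph, lambda = 2)
    est$proportions[target, "beech_other"]
  }
  vals <- vapply(c(0L, 5L, 15L, 30L), fit_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("centroid extraction is piecewise constant by district", {
  f <- fully_observed_survey()
  est <- fit_mrf_binomial(f$survey, f$land$graph)
  ext <- extract_at_centroids(est, f$land$munis)
  expect_identical(names(ext), c("muni_id", browsing_classes()))
  ## municipalities of one district share the value; re-aggregation by
  ## district reproduces the district estimates exactly
  di <- f$land$munis$district_id
  for (cl in browsing_classes()) {
    agg <- tapply(ext[[cl]], di, unique)
    expect_true(all(lengths(agg) == 1))
    expect_equal(unlist(agg)[f$land$graph$nodes],
                 est$proportions[, cl],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  m2 <- f$land$munis
  m2$district_id[1] <- "nonexistent"
  expect_error(extract_at_centroids(est, m2), "nonexistent")
})

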