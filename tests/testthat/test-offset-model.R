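test_that("collision table validation rejects malformed input", {
  toy <- data.frame(muni_id = "a", road_type = "residential", year = 2006L,
                    count = -1L, road_length = 1, red_deer = FALSE)
  expect_error(fit_offset_glm(toy), "negative")
  toy$count <- 1L; toy$road_length <- 0
  expect_error(fit_offset_glm(toy), "road_length")
  toy$road_length <- 1; toy$road_type <- "autobahn"
  expect_error(fit_offset_glm(toy), "road type")
})

test_that("score equations and stratum aggregation hold at the MLE", {
  w <- small_world()
  fit <- w$fit1
  X <- stats::model.matrix(fit$glm)
  r <- w$coll$count - fitted(fit$glm)
  expect_lt(max(abs(crossprod(X, r))), 1e-6)
  ## with full stratum interactions, fitted and observed totals agree
  ## within every road-type x year stratum
  stratum <- paste(w$coll$road_type, w$coll$year)
  tot_fit <- tapply(fitted(fit$glm), stratum, sum)
  tot_obs <- tapply(w$coll$count, stratum, sum)
  expect_lt(max(abs(tot_fit - tot_obs) / pmax(tot_obs, 1)), 1e-8)
})

test_that("stage-1 offset reproduces fitted means and hand arithmetic", {
  w <- small_world()
  off <- stage1_offset(w$fit1, w$coll)
  expect_lt(max(abs(exp(off) - fitted(w$fit1$glm))), 1e-12)

  ## single stratum: offset = beta0 + log(length) exactly
  toy <- data.frame(muni_id = c("a", "b"), road_type = "residential",
                    year = 2006L, count = c(3L, 5L),
                    road_length = c(1, 3), red_deer = FALSE)
  ft <- fit_offset_glm(toy)
  expect_equal(stage1_offset(ft, toy),
               coef(ft)[["(Intercept)"]] + log(toy$road_length),
               tolerance = 1e-12)
})

test_that("stratum rates: multiplicative red-deer factor, level checks", {
  w <- small_world()
  fit <- w$fit1
  r0 <- expected_dvc_per_km(fit, "secondary", 2006, red = FALSE)
  r1 <- expected_dvc_per_km(fit, "secondary", 2006, red = TRUE)
  expect_equal(r1 / r0, exp(coef(fit)[["red_deer"]]), tolerance = 1e-12)
  expect_error(expected_dvc_per_km(fit, "track", 2006), "road type")
  expect_error(expected_dvc_per_km(fit, "primary", 1999), "year")
  rates <- stratum_rate_table(fit)
  expect_equal(nrow(rates), 20L)
  expect_true(all(rates$dvc_per_km > 0))
})

test_that("coefficient estimates cover the simulation truth", {
  ## stage-1-only generator (no environmental effects, no overdispersion):
  ## each of the 11 coefficients within 3 SE of truth in >= 95% of reps
  n_rep <- 100L
  hits <- misses <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- landscape_config(grid_rows = 12, grid_cols = 12,
                            district_block = 4, seed = 1000L + r,
                            true_effects = default_true_effects()[0, ],
                            overdispersion_sd = 0, spatial_amplitude = 0)
    land <- generate_landscape(cfg)
    coll <- simulate_collisions(land$munis, cfg)
    fit <- fit_offset_glm(coll)
    est <- coef(fit)
    se <- sqrt(diag(fit$vcov))
    truth <- cfg$true_beta[c("intercept", "road_motorway", "road_primary",
                             "road_secondary", "road_tertiary", "year2009",
                             "red_deer", "road_motorway:year2009",
                             "road_primary:year2009",
                             "road_secondary:year2009",
                             "road_tertiary:year2009")]
    ok <- abs(est - truth) <= 3 * se
    hits <- hits + sum(ok); misses <- misses + sum(!ok)
  }
  expect_gte(hits / (hits + misses), 0.95)
})
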