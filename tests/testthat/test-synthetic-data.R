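test_that("landscape layout: grid, districts, graph", {
  cfg <- landscape_config(grid_rows = 2, grid_cols = 2, district_block = 2,
                          seed = 1)
  land <- generate_landscape(cfg)
  expect_equal(nrow(land$munis), 4L)
  expect_equal(length(unique(land$munis$district_id)), 1L)
  expect_equal(nrow(land$graph$edges), 0L)

  cfg <- landscape_config(grid_rows = 6, grid_cols = 6, district_block = 2,
                          seed = 1)
  land <- generate_landscape(cfg)
  expect_equal(length(land$graph$nodes), 9L)
  ## rook adjacency of a 3x3 block grid has 12 edges
  expect_equal(nrow(land$graph$edges), 12L)
  expect_false(any(land$graph$edges$from == land$graph$edges$to))
  ## every municipality in exactly one district, centroids unique
  expect_false(anyDuplicated(land$munis[, c("centroid_x", "centroid_y")]) > 0)
  expect_true(all(table(land$munis$muni_id) == 1))
  ## red-deer flag marks a nonempty strict subset of districts
  red <- unique(land$munis$district_id[land$munis$red_deer])
  expect_gt(length(red), 0)
  expect_lt(length(red), 9)
})

test_that("generators are deterministic given the seed", {
  cfg <- small_config(seed = 7)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a, b)
  expect_identical(simulate_collisions(a$munis, cfg),
                   simulate_collisions(b$munis, cfg))
  expect_identical(simulate_browsing_survey(a$graph, cfg),
                   simulate_browsing_survey(b$graph, cfg))
})

test_that("covariate surfaces are spatially autocorrelated", {
  land <- small_world()$land
  W <- grid_rook_weights(land$munis)
  for (v in c("bio1", "bio11", "meadows", "forest_edge", "oak_fir"))
    expect_gt(morans_i(land$munis[[v]], W), 0)
})

test_that("collision table: structure, exclusions, truth conservation", {
  w <- small_world()
  coll <- w$coll
  n <- nrow(w$land$munis)
  expect_lte(nrow(coll), 5L * 2L * n)
  expect_true(all(coll$road_type %in% road_types()))
  expect_true(all(coll$road_length > 0))
  expect_true(all(coll$count >= 0))
  ## structural zeros: municipality x road-type pairs without that road
  ## type produce no rows
  for (rt in road_types()) {
    absent <- w$land$munis$muni_id[w$land$munis[[paste0("len_", rt)]] == 0]
    expect_false(any(coll$muni_id %in% absent & coll$road_type == rt))
  }
  ## per-row truth components sum exactly to the total linear predictor
  tr <- attr(coll, "truth")
  expect_lt(max(abs(rowSums(tr[setdiff(names(tr), "eta")]) - tr$eta)),
            1e-10)
})

test_that("simulated counts match the Poisson mean under a null truth", {
  cfg <- landscape_config(grid_rows = 20, grid_cols = 20,
                          district_block = 4, seed = 11,
                          true_effects = default_true_effects()[0, ],
                          overdispersion_sd = 0, spatial_amplitude = 0)
  land <- generate_landscape(cfg)
  coll <- simulate_collisions(land$munis, cfg)
  mu <- coll$road_length * exp(attr(coll, "truth")$eta)
  ## total count vs total expectation, within 3 Poisson SE
  expect_lt(abs(sum(coll$count) - sum(mu)), 3 * sqrt(sum(mu)))
})

test_that("browsing survey: classes, missingness, binomial calibration", {
  w <- small_world()
  surv <- simulate_browsing_survey(w$land$graph, w$cfg)
  expect_true(all(surv$palatability_class %in% browsing_classes()))
  expect_true(all(surv$n_browsed >= 0 & surv$n_browsed <= surv$n_examined))

  ## dropping one class entirely removes it from the table
  cfg1 <- small_config(browsing_drop_fraction = c(
    spruce_pine = 1, oak_fir = 0, ash_maple_elm_linden = 0,
    beech_other = 0))
  land1 <- generate_landscape(cfg1)
  s1 <- simulate_browsing_survey(land1$graph, cfg1)
  expect_false("spruce_pine" %in% s1$palatability_class)
  expect_true(all(setdiff(browsing_classes(), "spruce_pine") %in%
                    s1$palatability_class))

  ## flat truth at logit 0: pooled browsing proportion near 1/2
  cfg0 <- landscape_config(
    grid_rows = 12, grid_cols = 12, district_block = 2, seed = 3,
    browsing_params = data.frame(class = browsing_classes(),
                                 base_logit = 0, amplitude = 0),
    browsing_drop_fraction = 0)
  land0 <- generate_landscape(cfg0)
  s0 <- simulate_browsing_survey(land0$graph, cfg0)
  ntot <- sum(s0$n_examined)
  expect_lt(abs(sum(s0$n_browsed) / ntot - 0.5), 3 * sqrt(0.25 / ntot))
})

test_that("harvest transform is rank-preserving and correlates with truth", {
  ## zero noise: district harvest ranking equals district-mean index ranking
  cfg <- small_config(harvest_params = list(hmax = 12, half_sat = 0.8,
                                            noise_sd = 0))
  land <- generate_landscape(cfg)
  tr <- true_dvc_index(land$munis, cfg)
  h <- simulate_harvest(land$munis, tr, cfg)
  dmean <- tapply(tr[land$munis$muni_id], land$munis$district_id, mean)
  expect_identical(rank(h$harvest_per_100ha),
                   rank(as.numeric(dmean[h$district_id])))

  ## default noise, 100 districts: positive significant rank correlation
  cfg2 <- landscape_config(grid_rows = 20, grid_cols = 20,
                           district_block = 2, seed = 4)
  land2 <- generate_landscape(cfg2)
  tr2 <- true_dvc_index(land2$munis, cfg2)
  h2 <- simulate_harvest(land2$munis, tr2, cfg2)
  dmean2 <- tapply(tr2[land2$munis$muni_id], land2$munis$district_id, mean)
  sc <- spearman_corr(as.numeric(dmean2[h2$district_id]),
                      h2$harvest_per_100ha)
  expect_gt(sc$rho, 0)
  expect_lt(sc$p_value, 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(landscape_config(grid_rows = 5, district_block = 4),
               "divide")
  expect_error(landscape_config(grid_rows = 1, grid_cols = 4,
                                district_block = 1), ">= 2")
  expect_error(landscape_config(p_no_road = c(motorway = 1, primary = 0,
                                              secondary = 0, tertiary = 0,
                                              residential = 0)),
               "\\[0, 1\\)")
  expect_error(landscape_config(true_effects = data.frame(
    covariate = "not_a_var", fun = "sin", amplitude = 1)),
    "unknown covariate")
  expect_error(landscape_config(true_effects = data.frame(
    covariate = "bio1", fun = "cubic", amplitude = 1)),
    "function tag")
  ## unknown covariate reported at simulation time as well
  w <- small_world()
  cfg_bad <- w$cfg
  cfg_bad$true_effects <- data.frame(covariate = "bio1", fun = "sin",
                                     amplitude = 1)
  munis_bad <- w$land$munis
  munis_bad$bio1 <- NULL
  expect_error(simulate_collisions(munis_bad, cfg_bad), "unknown covariate")
})
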