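test_that("index is one under an empty selected set", {
  fit <- small_boost()
  w <- small_world()
  idx <- compute_index(fit, w$land$munis, selected = character(0))
  expect_true(all(idx$index == 1))
  expect_true(all(idx$climate == 1))
})

test_that("group factors multiply to the index", {
  fit <- small_boost()
  w <- small_world()
  idx <- compute_index(fit, w$land$munis, year = 2006L,
                       include_spacetime = TRUE,
                       include_overdispersion = TRUE)
  prod_all <- apply(as.matrix(idx[, dvcrisk:::index_groups()]), 1, prod)
  expect_lt(max(abs(prod_all - idx$index)), 1e-10)
  expect_true(all(idx$index > 0))
})

test_that("regrouping a learner moves its factor, not the product", {
  fit <- small_boost()
  w <- small_world()
  nm <- vapply(fit$learners, `[[`, "", "name")
  g1 <- stats::setNames(vapply(fit$learners, `[[`, "", "group"), nm)
  g2 <- g1
  g2[["bio11"]] <- "landuse"
  d1 <- decompose_index(fit, w$land$munis, grouping = g1)
  d2 <- decompose_index(fit, w$land$munis, grouping = g2)
  gl <- dvcrisk:::index_groups()
  p1 <- apply(as.matrix(d1[, gl]), 1, prod)
  p2 <- apply(as.matrix(d2[, gl]), 1, prod)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(d1$climate, d2$climate)))
  ## restricting the selected set to one group leaves the others at 1
  idx_cl <- compute_index(fit, w$land$munis,
                          selected = nm[g1 == "climate"])
  expect_true(all(idx_cl$landuse == 1))
  expect_true(all(idx_cl$browsing == 1))
})

test_that("spatio-temporal factor is null in 2006", {
  fit <- small_boost()
  w <- small_world()
  idx06 <- compute_index(fit, w$land$munis, year = 2006L,
                         include_spacetime = TRUE)
  expect_true(all(idx06$spacetime == 1))
})

test_that("risk classification: separated clusters, ordering, errors", {
  idx <- data.frame(muni_id = letters[1:6], index = c(1, 1, 1, 2, 2, 2))
  cls <- classify_risk(idx, k = 2, seed = 1)
  expect_equal(cls$classes$class, c(1, 1, 1, 2, 2, 2))
  expect_equal(cls$centers, c(1, 2))
  expect_error(classify_risk(idx, k = 5), "distinct")
  expect_error(classify_risk(idx, k = 1), ">= 2")

  ## k-means labels beat random labelings in within-class sum of squares
  set.seed(8)
  x <- c(rnorm(20, 0), rnorm(20, 3), rnorm(20, 7))
  cl <- classify_risk(x, k = 3, seed = 2)
  wss <- function(lab) sum(tapply(x, lab, function(v) sum((v - mean(v))^2)))
  w0 <- wss(cl$classes$class)
  rnd <- replicate(1000, wss(sample(cl$classes$class)))
  expect_true(all(w0 <= rnd))
  ## labels ordered by class center
  expect_true(all(diff(tapply(x, cl$classes$class, mean)) > 0))
})

test_that("missing selected covariates are reported", {
  fit <- small_boost()
  w <- small_world()
  m2 <- w$land$munis
  m2$bio11 <- NULL
  expect_error(compute_index(fit, m2), "bio11")
})

test_that("estimated index recovers the generator truth", {
  w <- study_world()
  fit <- study_fit()
  stab <- study_stability()
  idx <- compute_index(fit, w$land$munis, year = 2006L,
                       selected = stab$selected)
  truth <- true_dvc_index(w$land$munis, w$cfg, year = 2006L)
  expect_gt(spearman_corr(idx$index, as.numeric(truth))$rho, 0.8)
})

test_that("group variability mirrors the generator's amplitude ordering", {
  w <- study_world()
  fit <- study_fit()
  stab <- study_stability()
  idx <- compute_index(fit, w$land$munis, year = 2006L,
                       selected = stab$selected)
  sds <- attr(idx, "group_log_sd")
  expect_gt(sds[["climate"]], sds[["landuse"]])
  expect_gt(sds[["landuse"]], sds[["browsing"]])
  expect_gt(sds[["browsing"]], 0)
})
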