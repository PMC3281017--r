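## Shared fixtures, built once per test session and memoised: a small
## world for unit tests, the reference study world (sparse truth) and a
## function-recovery world, each with the stage-1 fit and offset attached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env))
    assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

make_world <- function(cfg) {
  land <- generate_landscape(cfg)
  coll <- simulate_collisions(land$munis, cfg)
  fit1 <- fit_offset_glm(coll)
  off <- stage1_offset(fit1, coll)
  list(cfg = cfg, land = land, coll = coll, fit1 = fit1, off = off,
       data = boost_data(coll, land$munis))
}

small_config <- function(seed = 42, ...) {
  landscape_config(grid_rows = 8, grid_cols = 8, district_block = 2,
                   seed = seed, ...)
}

small_world <- function() fixture("small_world", function() {
  make_world(small_config())
})

small_boost <- function() fixture("small_boost", function() {
  w <- small_world()
  fit_boost(w$data, w$off, mstop = 120L)
})

## Reference study world: 20 x 20 municipalities, sparse default truth
## (6 signal covariates of 23), road presence 0.4 per category, so about
## 800 collision rows per survey year.
study_config <- function(seed = 2006, ...) {
  landscape_config(seed = seed,
                   p_no_road = c(motorway = 0.6, primary = 0.6,
                                 secondary = 0.6, tertiary = 0.6,
                                 residential = 0.6), ...)
}

study_world <- function() fixture("study_world", function() {
  make_world(study_config())
})

study_oob <- function() fixture("study_oob", function() {
  w <- study_world()
  select_mstop_oob(w$data, w$off, grid = seq(0L, 1000L, by = 25L),
                   n_boot = 10L, seed = 1L)
})

study_fit <- function() fixture("study_fit", function() {
  w <- study_world()
  fit_boost(w$data, w$off, mstop = max(study_oob()$mstop, 25L))
})

study_stability <- function() fixture("study_stability", function() {
  w <- study_world()
  stability_select(w$data, w$off, m_iter = max(study_oob()$mstop, 25L),
                   n_subsamples = 50L, threshold = 0.5, seed = 1L)
})

## Function-recovery world: same scale, but the truth consists of exactly
## one sine, one quadratic and one monotone effect at the default climate
## amplitude.
recovery_config <- function(seed = 1003) {
  study_config(seed = seed, true_effects = data.frame(
    covariate = c("bio11", "bio18", "bio6"),
    fun = c("sin", "quadratic", "monotone"),
    amplitude = c(0.6, 0.6, 0.6)))
}

recovery_world <- function() fixture("recovery_world", function() {
  make_world(recovery_config())
})

recovery_fit <- function() fixture("recovery_fit", function() {
  w <- recovery_world()
  oob <- select_mstop_oob(w$data, w$off, grid = seq(0L, 1000L, by = 25L),
                          n_boot = 10L, seed = 1L)
  list(oob = oob, fit = fit_boost(w$data, w$off,
                                  mstop = max(oob$mstop, 25L)))
})

## Small pipeline run shared between the orchestration tests.
pipeline_settings <- function(seed = 9) {
  pipeline_config(
    landscape = small_config(seed = 5),
    mstop_grid = seq(0L, 150L, by = 25L), n_boot = 4L,
    n_subsamples = 8L, seed = seed)
}

pipeline_run <- function() fixture("pipeline_run", function() {
  dir <- file.path(tempdir(), "dvcrisk-pipeline-run")
  list(dir = dir, report = run_pipeline(pipeline_settings(), out_dir = dir))
})

## Independent oracle: maximize the Poisson offset log-likelihood by
## general-purpose optimization from several starts (never IRLS).
bruteforce_poisson <- function(X, y, offset, n_starts = 5L) {
  negll <- function(beta) {
    eta <- offset + drop(X %*% beta)
    sum(exp(eta)) - sum(y * eta)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) rep(0, ncol(X)) else
      withr::with_seed(s, stats::rnorm(ncol(X), 0, 0.5))
    opt <- stats::optim(start, negll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  best$par
}
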