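# dvcrisk

Model-based assessment of deer–vehicle collision (DVC) risk at the scale
of administrative municipalities.

Collisions with roe deer are both a road-safety problem and — because car
drivers sample the deer population unselectively — one of the cheapest
available relative indices of deer density. `dvcrisk` implements a
two-stage count-regression pipeline for municipality-level collision
records, aimed at wildlife managers, road-safety planners and
biostatisticians who want a decomposable, mapped risk index rather than an
unattainable absolute density estimate.

## The model

**Stage 1 — mandatory parametric baseline.** Counts per municipality
× road category × survey year are Poisson with log link and the log road
length as offset:

    log mu = log L + beta0 + beta_road + beta_year + beta_road:year + beta_red * red

(11 parameters under treatment coding; `red` flags red-deer management
districts). Dividing by `L` gives expected DVCs *per kilometer* by
stratum. These effects are mandatory: fitted first, by maximum
likelihood, and never subject to selection or penalization.

**Stage 2 — boosted additive deviations.** Deviations from the stage-1
predictor (which enters as a fixed offset) are modelled by an additive
Poisson model with smooth P-spline terms for 9 climate and 10 land-use
covariates, *monotone* P-splines for 4 browsing intensities, a bivariate
spatial surface of the municipality centroids, a 2009-only
spatio-temporal surface, and per-observation ridge intercepts acting as an
overdispersion term. Estimation is component-wise gradient boosting with
all base-learners calibrated to equal effective degrees of freedom; the
number of iterations is selected by out-of-bootstrap risk and the
relevant terms by stability selection over municipality half-samples.

**DVC index.** The exponentiated nonparametric part is a multiplicative
risk index relative to the stage-1 baseline (0.5 = half, 2.0 = twice the
baseline expectation). It factorizes exactly into climate × land-use ×
browsing × spatial contributions, is classified into risk classes by
k-means (default 7), and is validated externally against district harvest
densities via Spearman rank correlation and a LOWESS trend. Browsing
survey proportions are smoothed beforehand over the district adjacency
graph by an intrinsic-CAR (Markov random field) binomial model.

A synthetic-landscape generator with known ground truth (grid
municipalities, district blocks, smooth Gaussian-field covariates, sparse
nonlinear effects, binomial browsing surveys, saturating harvest relation)
makes the whole pipeline testable without any external data.

## Worked example

```r
library(dvcrisk)

cfg  <- landscape_config(grid_rows = 10, grid_cols = 10,
                         district_block = 2, seed = 7)
land <- generate_landscape(cfg)
coll <- simulate_collisions(land$munis, cfg)

fit1 <- fit_offset_glm(coll)                      # stage 1
subset(stratum_rate_table(fit1), !red_deer & year == 2006)
#>     road_type year red_deer dvc_per_km
#> 1    motorway 2006    FALSE 0.04831742
#> 2     primary 2006    FALSE 0.19671128
#> 3   secondary 2006    FALSE 0.38751920
#> 4    tertiary 2006    FALSE 0.27617310
#> 5 residential 2006    FALSE 0.08249711
```

The stratum table reads as expected DVCs per km and year: secondary roads
are the most dangerous per kilometer, fenced motorways the least.

```r
off  <- stage1_offset(fit1, coll)
d    <- boost_data(coll, land$munis)
oob  <- select_mstop_oob(d, off, grid = seq(0, 300, 25), n_boot = 5, seed = 1)
oob
#> Out-of-bootstrap selection: mstop = 175 (grid 0..300, 5 replicates)

fit2 <- fit_boost(d, off, mstop = oob$mstop)      # stage 2
stab <- stability_select(d, off, m_iter = oob$mstop,
                         n_subsamples = 20, seed = 1)
stab
#> Stability selection (20 subsamples, threshold 0.50)
#>   selected: bio6, bio11, bio18, bio19, industry, urban, complex_habitats,
#>             conifer_forest, overdispersion

idx <- compute_index(fit2, land$munis, year = 2006, selected = stab$selected)
summary(idx$index)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.3713  0.6174  0.8702  1.0145  1.3094  2.4313

classify_risk(idx, k = 7, seed = 1)
#> Risk classification: 7 classes, centers 0.523, 0.749, 0.992, 1.276,
#>                      1.518, 1.77, 2.335

harvest <- simulate_harvest(land$munis, true_dvc_index(land$munis, cfg), cfg)
validate_against_harvest(idx, land$munis, harvest)
#> Index-harvest validation: 25 districts, Spearman rho = 0.681 (p = 0.00018)
```

A municipality with index 0.87 (the median above) is expected to see 87%
of the baseline stratum rate per km; the least-risky class center sits
near 0.5, the most-risky near 2.3. The positive, significant rank
correlation with simulated harvest densities is the external-validation
step. `predict_partial(fit2, "bio11", ...)` returns any term's centered
partial contribution and its multiplicative (`exp`) scale for effect
plots; `decompose_index()` splits the index into group factors whose
product is exactly the index.

`run_pipeline(pipeline_config(...), out_dir = "...")` chains all stages
(simulate → offset GLM → out-of-bootstrap selection → boosting →
stability selection → browsing smoothing → index → classification →
harvest validation) and writes every artifact as CSV/JSON. A thin command
line sits in `exec/dvcrisk` (`simulate`, `fit-offset`, `browsing`,
`validate`, `run`).

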