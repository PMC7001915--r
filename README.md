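# richworld

Modelling gridded species richness from environmental drivers with a
small, fully interpretable feed-forward neural network — and testing every
stage of that analysis on synthetic worlds whose driver–richness structure
is known exactly.

## The problem

Global biodiversity analyses ask how much of the spatial pattern in
species richness is explained by environment: energy, production and its
seasonality, temperature, precipitation or oxygen, elevation or depth.
A typical modern pipeline (i) assembles richness on an equal-area grid —
from expert range maps on land, from screened point occurrence records at
sea; (ii) engineers per-cell features from driver layers and monthly
climate series; (iii) fits a flexible regression (here a neural network)
of ln-transformed richness on the scaled features; and (iv) interrogates
the fitted model with variable importance, partial dependence and residual
diagnostics. Each stage has failure modes that are invisible on real data
because the truth is unknown. `richworld` implements the full pipeline
*and* a seeded synthetic-world generator, so every stage can be validated
against known generative structure before being pointed at real data.

## What is in the box

* **Synthetic worlds** (`simulate_world()`): cylindrical equal-area grids
  (default 50 km cells), spatially autocorrelated driver fields, monthly
  series with 12- and 6-month seasonal components, niche-derived species
  ranges, point occurrence records with log-uniform record counts in
  [1, 1000], and richness surfaces — either stacked ranges or a known
  driver→richness function plus noise.
* **Occurrence screening** (`screen_species()`,
  `min_sufficient_records()`, `rarefaction_curve()`): the resampled
  range-recovery statistic (smallest n such that >95% of n-record
  resamples recover the species' global 1st–99th percentile latitudinal /
  thermal interval), the 41-record filter, and analytic (hypergeometric)
  or Monte-Carlo rarefaction curves per 20° latitude bin.
* **Feature engineering** (`build_feature_table()`,
  `summarize_series()`, `seasonal_intensity()`): intra-/inter-annual
  mean, sd, range and CV summaries; 1%/99% quantile truncation; 0–1
  rescaling with stored provenance; Morlet continuous-wavelet 6- and
  12-month seasonal-intensity metrics (scale-rectified power,
  cone-of-influence aware).
* **The model** (`rich_ann()`): a rectifier MLP — 3 hidden layers × 10
  units, inverted dropout 0.2, momentum-0.9 minibatch SGD, batch 128,
  squared-error loss — fit on an 80/20 split with 5-fold cross-validated
  hyperparameter selection (`cross_validate()`). The response is
  ln(x+1)-transformed, 0–1 rescaled richness:

  `ln(S_i + 1) ~ f_theta(x_i1, ..., x_ip)`, `x_ij` in [0, 1].

  S3 methods: `print`, `summary`, `coef`, `predict`, `residuals`,
  `fitted`, `plot`, plus `evaluate()` (R², RMSE) and
  `predict_surface()`.
* **Interpretation** (`permutation_importance()`,
  `partial_dependence()`, `pairwise_loess_ensemble()`,
  `residual_map()`, `zonal_profile()`,
  `empirical_semivariogram()`): bootstrapped noise-perturbation ΔR²
  importance (500 refits on random subsets by default), 1- and 2-driver
  partial-dependence surfaces, resampled loess curve ensembles with 95%
  quantile bands, observed-minus-predicted maps, 2° zonal means and
  residual semivariograms.
* **Pipeline** (`run_pipeline()`, `pipeline_config()`): one seeded
  config drives generate → screen (marine) → featurize → fit → interpret
  per domain (terrestrial and marine are modelled by two separate
  networks), writing CSV/JSON/YAML artifacts and a manifest with md5
  checksums; runs are byte-reproducible.

## Worked example

```r
library(richworld)

# a seeded world: ~3,000 cells, 30 drivers (3 causal), known function
cfg <- world_config(seed = 21, noise_sd = 0.05, n_years = 5)
w <- simulate_world(cfg, extent = c(-20, 20, -18, 18), cell_km = 75)

tab <- build_feature_table(w$drivers$static[sprintf("driver%02d", 1:30)],
                           w$richness, w$grid)
fit <- rich_ann(data = tab,
                config = ann_config(dropout = 0, epochs = 300))
print(fit)
#> Richness feed-forward network
#>   features: 30; architecture: 3 x 10 relu -> 1
#>   train: n = 2544, R2 = 0.981, RMSE = 0.0263
#>   test:  n = 636, R2 = 0.977, RMSE = 0.0300
```

The test-set R² of 0.98 says the 3×10 rectifier network recovers ~98% of
the variance of the known driver→richness function from 30 candidate
features, of which 27 are pure distractors. Importance then identifies
the causal drivers:

```r
imp <- permutation_importance(tab, ann_config(dropout = 0.1, epochs = 150),
                              n_reps = 50, subset_fraction = 0.5, seed = 1)
head(rank_importance(imp), 4)
#>    feature     median         q025      q975 rank
#> 1 driver02 0.20041837 0.0035876000 0.3558504    1
#> 2 driver01 0.13145122 0.0088116391 0.3197224    2
#> 3 driver03 0.07832823 0.0019305497 0.1570194    3
#> 4 driver15 0.03901994 0.0004979673 0.1233058    4
```

The three causal drivers rank first by median ΔR² — the drop in held-out
explained variance when that feature is replaced with resampled noise in
50 refit ensembles. (On this compact ~3,000-cell world the leading
distractor is not far behind the weakest causal driver: smooth null
fields genuinely explain some variance by chance spatial association at
this grid size. The package's recovery analyses run on ~20,000-cell
worlds, where distractor medians fall within ±0.01 of zero.)

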