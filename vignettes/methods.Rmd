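---
title: "Methods: synthetic worlds, screening, phenology features and the richness network"
author: "richworld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic worlds, screening, phenology features and the richness network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`richworld` implements a complete gridded richness-modelling pipeline —
generation or ingestion of driver and richness layers, occurrence-record
screening, feature engineering with wavelet phenology metrics, a small
feed-forward network, and a model-interrogation suite — together with the
synthetic worlds needed to validate each stage against known truth. This
vignette records the models, the parameter choices that matter, and the
design decisions taken where the protocol left the choice open.

## 1. The grid and the synthetic world

All layers live on a Lambert cylindrical equal-area grid (x = R·λ,
y = R·sin φ, Earth radius R = 6371 km) tiled with square cells, 50 km by
default, stored row-major from the southern edge. Equal cell area is what
makes per-cell richness counts and zonal means comparable across
latitudes.

`simulate_world()` produces, from one seeded `world_config()`:

* **Driver fields.** White noise smoothed with a separable Gaussian
  kernel; the kernel sd in cells is the correlation length (default 5
  cells, i.e. ~250 km at 50-km cells — the scale of synoptic
  environmental structure). Kernel weights are renormalised at the grid
  edges. Fields are min–max rescaled to [0, 1], matching the scaled
  drivers the model consumes. A Gaussian-smoothing construction was
  chosen over spectral synthesis for O(cells) cost and simplicity.
* **Monthly series** (`temperature`, `production`, `insolation`): a
  spatial baseline (temperature and insolation get a latitudinal mean
  gradient) plus 12-month and 6-month cosine components with configured
  amplitudes, an independent random phase per cell, and white noise.
  Ten years of months by default.
* **Domains.** One elevation-like field is thresholded at a configurable
  land fraction (default 0.3), splitting cells into `land` and `ocean`;
  the two domains are modelled separately throughout, and occurrence
  screening applies to the marine side only.
* **Species ranges.** Each species draws a niche centre at a random cell
  of its domain and half-widths on two axes — mean temperature and
  latitude (folded-normal, scales `niche_breadth = c(4, 12)`); its range
  is every domain cell satisfying both intervals. Ranges are cell sets,
  not polygons. Empty draws are retried up to a cap. Stacking ranges
  (`stack_ranges_to_richness()`) gives integer richness; the thermal and
  latitudinal niche axes make the screening statistics meaningful.
* **Occurrences.** Per-species record counts are log-uniform on
  [1, 1000] (the domain over which record sufficiency is assessed);
  records pick uniform cells of the range, jitter uniformly within the
  cell, and carry the cell's mean temperature as their thermal value
  (the generator must attach *some* thermal value to each record; the
  cell's climatological mean is the simplest defensible choice).
* **Known richness function.** The default
  `default_richness_function()` is S = expm1(2·(g₁+g₂+g₃)) with
  g₁ a Gaussian optimum exp(−(x−0.6)²/(2·0.18²)), g₂ = x, g₃ = x² over
  the first three drivers. The components are additive on the ln(x+1)
  scale — multiplicative suitability filtering on the richness scale —
  because the pipeline models ln richness: this is what makes "additive
  world" and partial-dependence component recovery well defined on the
  modelled response, and it yields the right-skewed richness surfaces
  (roughly 0–400 species per cell) real data show. Noise of sd
  `noise_sd` (default 0.05) is added on the ln(x+1) scale:
  S = expm1(log1p(f) + ε), clamped at zero, so the modelled response
  carries additive Gaussian noise of exactly that sd and the recovery
  ceiling 1 − σ²/Var(y) is exact. With `noise_sd = 0` the configured
  function is returned exactly.

What the generator does *not* emulate: sampling effort gradients,
taxonomic error, range-map subjectivity, temporal nonstationarity, and
driver collinearity structure beyond what smoothing induces. Tests that
pass on these worlds therefore establish the *machinery* — not that real
richness is predictable to any particular R².

## 2. Occurrence screening

For each species the global latitudinal and thermal intervals are the 1st
to 99th percentiles of its records (linear-interpolation / type-7
percentiles throughout; the convention is stated because it matters at
small n). `min_sufficient_records()` finds the smallest n such that, over
`reps` resamples of n records drawn without replacement, more than
`coverage` (default 0.95, strictly) of the resampled intervals *recover*
the global interval — each resampled endpoint must reach to within
`tol` × width of the corresponding global endpoint.

Two choices deserve emphasis:

* **Direction.** A resampled interval is always *contained* in the global
  one for small n (two records give a near-zero-width interval), so a
  containment criterion is satisfied trivially at n = 2 and cannot define
  a minimum. Sufficiency must be the reverse: enough records that the
  estimated range *reaches* the true range. Under this reading success
  probability rises to 1 at n = n_records and the default literal upward
  scan returns the exact first crossing. A bisection option
  (`method = "binary"`) is faster but assumes global monotonicity; on
  duplicate-heavy data the type-7 interpolation weight makes the success
  curve locally sawtoothed in n and bisection can overshoot the first
  crossing by several records, so the exact scan is the default. Per-n
  resampling seeds keep the two methods mutually consistent where
  monotonicity holds.
* **Tolerance.** `tol` is a genuine free parameter. Near-zero tolerances
  demand nearly all records for continuous data (the minimum approaches
  75% of n_records), which would make any fixed record-count cutoff in
  the tens meaningless. The default `tol = 0.1` places the statistic at
  the scale of tens of records on clustered occurrence data — the scale
  at which published sufficiency medians (~33–41 records) and the
  41-record retention threshold operate. The parameter is exposed for
  sensitivity analysis.

`screen_species()` applies the global record-count threshold (default
41) and reports per-species counts and intervals; screening an
already-screened set is a no-op. `median_min_sufficient()` summarises
per-species minima as median ± median absolute deviation (the spread
convention is ours; "±" was otherwise undefined).

Rarefaction (`rarefaction_curve()`) is computed analytically from the
hypergeometric identity E[S(n)] = Σᵢ (1 − C(N−Nᵢ, n)/C(N, n)) or by
Monte Carlo; `latitudinal_rarefaction()` bins records into 20° latitude
bands. Bin edges sit at multiples of 20° but the equator is always an
edge, so hemispheres never share a bin; the polar bins are clipped to
[−90, −80) and [80, 90]. Bins are half-open from below, the northernmost
closed.

## 3. Features and wavelet phenology

`summarize_series()` computes intra-annual statistics on the 12-month
climatology (per-cell calendar-month means across years — so they are
invariant to permuting whole years) and inter-annual statistics across
per-year annual sums. CV returns 0 with |mean| < 1e−9. "Range" is
max − min of the aggregate values.

Seasonal intensity uses the analytic Morlet wavelet, ω₀ = 6, in the
Torrence–Compo frequency-domain form, on a geometric scale ladder with 12
sub-octaves per octave. A *band* is the set of ladder scales whose
equivalent Fourier period lies within ±1 month of the target (6 or 12
months). Per cell, the series is mean-removed, power inside the
cone of influence (e-folding time √2·s at each end) is excluded from the
time average, and the reported intensity is the *scale-rectified* band
mean ⟨|W(s,t)|²⟩/s. Rectification matters: the unrectified spectrum
over-weights short periods, so equal-amplitude 6- and 12-month
components would not read as equal intensity, and dominant-period
ordering would disagree with a Fourier periodogram. With rectification,
band ordering matches the FFT periodogram oracle on all synthetic
two-tone tests, equal-amplitude tones agree within ~25% (the residual
asymmetry is the ±1-month band being relatively wider at 6 months), and
power scales with amplitude squared.

`build_feature_table()` assembles one row per domain cell: features are
truncated at the 1%/99% quantiles (computed over the domain's cells
only, since domains are modelled separately; elevation/depth are exempt)
then min–max rescaled to [0, 1]; the response is 0–1 rescaled
ln(richness + 1). All transform parameters are stored so predictions
invert exactly back to richness.

## 4. The network

`rich_ann()` fits the reference protocol: three hidden layers of ten
rectifier units, inverted dropout 0.2 on hidden activations (inference
deterministic), plain momentum SGD (momentum 0.9) on squared error,
batch size 128, ten epochs, 80/20 train/test split, and
`cross_validate()` for 5-fold hyperparameter selection on the training
rows (selection minimises mean fold RMSE with fold-RMSE variance as the
tie-breaker, then model size, then candidate order; both statistics are
reported so either reading of "minimise cross-validation RMSE variance"
can be audited). Weights are fan-in-scaled uniform; the trainer is
compiled (RcppArmadillo) and driven by R's RNG, so fits are
bit-reproducible under `set.seed`-style seeds. A pure-R reference
trainer (`.mlp_train_r`) is retained as an independent check on the
compiled path.

Numerical choices worth recording:

* **Learning rate.** Unstated in the protocol. With momentum 0.9 the
  effective step is ~10× the nominal rate; on [0, 1]-scaled features
  rates ≥ 0.05 sit in an oscillatory regime (fits plateau near R² ≈ 0),
  while 0.01–0.02 converge cleanly. The default is 0.02. An optional
  per-epoch decay factor (`lr_decay`) is available; the default (1)
  keeps the stated protocol.
* **Dropout and convergence.** Dropout 0.2 on 10-unit layers is a strong
  regulariser: on noiseless synthetic worlds the dropout-regularised
  optimum caps test R² near 0.76 *regardless of epochs or rate* —
  measured, not assumed. Recovery analyses that ask "can this
  architecture represent the generative function?" therefore train the
  same 3×10 architecture to convergence *without* dropout
  (`ann_config(dropout = 0, epochs = 800, learning_rate = 0.02)`),
  reaching test R² ≈ 0.99 on ~20,000-cell noiseless worlds. The
  protocol default (dropout 0.2, 10 epochs) remains the package default
  for data-facing fits.
* **Degenerate configurations.** `nodes_per_layer = 0` (or
  `hidden_layers = 0`) is an explicit intercept-only baseline predicting
  the training mean; it exists so cross-validation can demonstrate that
  the network is preferred on nonlinear worlds.

## 5. Interpretation suite

* **Importance** (`permutation_importance()`): per replicate, draw a
  random row subset (default fraction 0.8; the recovery analyses use
  0.15 of a ~20,000-cell world so each of 500 refits sees an independent
  ~3,000-row sample), split it 80/20, train a fresh network, then for
  each feature replace its held-out column with that feature's own
  values resampled with replacement (breaking the association while
  preserving the marginal; a uniform-noise alternative is a flag) and
  record ΔR² = baseline − perturbed on the held-out rows. Medians and
  quantiles across replicates summarise; `rank_importance()` orders by
  median with alphabetical tie-break.
* **Partial dependence** (`partial_dependence()`): data-distribution
  averaging (set the feature(s) to a grid value in every row and average
  predictions) rather than pinning other features at their means,
  because the surfaces are meant to show the network's approximation as
  inputs co-vary. Grid points outside the inner 90% of the feature's
  marginal (quantiles 0.05–0.95) are flagged uncovered: partial
  dependence extrapolates unreliably in sparse tails, and that trimming
  convention is the standard default. When a recovered curve is compared
  with a generative component, the component is evaluated in raw driver
  units by inverting the feature's stored truncation-and-rescale
  provenance — correlating against the scaled coordinate silently
  applies an affine distortion of the component's shape.
* **Loess ensembles** (`pairwise_loess_ensemble()`): 100 subsamples of
  10,000 rows (clamped with a warning on smaller tables), a quadratic
  loess (span 0.75) per subsample evaluated on a fixed grid, pointwise
  median and 2.5%/97.5% quantiles.
* **Residual diagnostics**: `residual_map()` is observed − predicted
  (positive = underpredicted, i.e. unexpectedly species-rich);
  `zonal_profile()` averages over half-open 2° latitude bins and its
  cell-count-weighted bin means recombine exactly to the global mean;
  `empirical_semivariogram()` computes γ(h) = ½⟨(zᵢ−zⱼ)²⟩ over centroid
  distances on the equal-area plane, exhaustively below 10⁴ cells and on
  a seeded 10⁶-pair subsample above.

## 6. Pipeline and reproducibility

`run_pipeline()` executes generate → screen (ocean only; terrestrial
richness comes from stacked ranges, marine richness from ranges of
species that survive the record filter) → featurize → fit → interpret for
each domain, writing all artifacts as CSV/JSON/YAML plus a
`manifest.json` of stage seeds, fit metrics and md5 checksums. Stage
seeds are derived deterministically from the global seed and the stage
name, so adding a stage never perturbs earlier randomness; manifests
contain no timestamps or absolute paths and are byte-identical across
runs with one seed. Rasters are exchanged as long-format CSV (cell id,
row/col, lon/lat, value) rather than binary raster formats, keeping
every artifact diff-able and dependency-free.

Problem sizes used by the shipped analyses: the demo pipeline runs a
~100×100-cell world with 200 species, a 150-epoch fit (a ~10,000-cell
table sees few gradient updates per epoch, so the 10-epoch protocol
default would be far from converged at this size) and reduced
interpretation replicate counts (10 importance refits, 20 loess
resamples per domain);
the recovery analyses use ~20,000-cell worlds, 800-epoch converged fits,
and 10 × 50 importance replicates; screening-oracle comparisons use 20
species of 100–1000 records at 10⁴ resamples. These sizes were chosen so
the full validation battery runs on a single CPU in tens of minutes
while keeping every Monte-Carlo comparison far above its noise floor.

## 7. Known limitations

* The synthetic driver fields are isotropic and stationary; real
  environmental fields are neither. Importance and partial-dependence
  nulls on *small* worlds are optimistic about chance spatial
  association — on compact grids a smooth distractor field can genuinely
  explain a percent or two of variance; the shipped recovery analyses
  use ~20,000-cell worlds where this effect is below 0.01 ΔR².
* The screening statistic's absolute scale depends on the capture
  tolerance (see §2); comparisons across datasets should hold `tol`
  fixed.
* Dropout-regularised small networks under-fit sharp response features
  (the Gaussian-optimum component is recovered with correlation ~0.96,
  the smooth components ~0.99); widening the band of partial-dependence
  evaluation into uncovered tails degrades recovery further, which is
  why uncovered points are flagged.
* No spatial-autocorrelation covariate is offered: residual spatial
  structure is deliberately *presented* (maps, semivariograms) rather
  than absorbed, so unmodelled processes remain visible.
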