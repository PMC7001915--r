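# shared fitted model on the mid-size noiseless world (30 features:
# 3 causal drivers + 27 distractors)
fitted_mid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- feature_table_of(mid_world_noiseless())
      cache <<- rich_ann(data = tab,
                         config = ann_config(epochs = 300, dropout = 0,
                                             seed = 55))
    }
    cache
  }
})

test_that("importance reps are reproducible and rank the causal drivers first", {
  tab <- feature_table_of(mid_world_noiseless())
  cfg <- ann_config(epochs = 60, dropout = 0.1, seed = 1)
  imp <- permutation_importance(tab, cfg, n_reps = 8,
                                subset_fraction = 0.5, seed = 77)
  imp2 <- permutation_importance(tab, cfg, n_reps = 8,
                                 subset_fraction = 0.5, seed = 77)
  expect_identical(imp$reps, imp2$reps)
  rk <- rank_importance(imp)
  # rank list is a permutation of the feature set
  expect_setequal(rk$feature, attr(tab, "feature_names"))
  # the three causal drivers hold the top three median ranks
  expect_setequal(rk$feature[1:3], sprintf("driver%02d", 1:3))
})

test_that("identical importance distributions rank alphabetically", {
  fake <- structure(list(reps = data.frame(
    rep = rep(1:4, 2),
    feature = rep(c("zeta", "alpha"), each = 4),
    delta_r2 = rep(c(0.1, 0.2, 0.3, 0.4), 2))), class = "rw_importance")
  rk <- rank_importance(fake)
  expect_equal(rk$feature, c("alpha", "zeta"))
})

test_that("partial dependence is flat for null features and consistent in 2d", {
  fit <- fitted_mid()
  pd0 <- partial_dependence(fit, vars = "driver15", resolution = 15)
  dev <- pd0$yhat[pd0$covered] - mean(pd0$yhat[pd0$covered])
  # flatness bound scaled to this compact world: chance spatial
  # association of a smooth null field is larger than on the full-size
  # worlds the recovery analyses use
  expect_lt(max(abs(dev)), 0.05)
  # unknown features error
  expect_error(partial_dependence(fit, vars = "nope"), "unknown feature")
  # a 2-feature surface row matches the 1-feature curve with the other pinned
  pd2 <- partial_dependence(fit, vars = c("driver01", "driver02"),
                            resolution = 8)
  y0 <- sort(unique(pd2$y))[3]
  row3 <- pd2[pd2$y == y0, ]
  tab <- fit$data
  tabp <- tab
  tabp$driver02 <- y0
  pd1 <- partial_dependence(fit, data = tabp, vars = "driver01",
                            resolution = 8)
  # same evaluation grid up to range differences; compare via interpolation
  interp <- stats::approx(pd1$x, pd1$yhat, xout = row3$x, rule = 2)$y
  expect_equal(row3$yhat, interp, tolerance = 0.02)
})

test_that("partial dependence recovers an additive component's shape", {
  fit <- fitted_mid()
  pd <- partial_dependence(fit, vars = "driver02", resolution = 20)
  sel <- pd$covered
  expect_gt(stats::cor(pd$yhat[sel], pd$x[sel]), 0.95)  # linear component
})

test_that("loess ensembles recover a linear truth with ordered bands", {
  set.seed(61)
  n <- 4000
  df <- data.frame(x = runif(n))
  df$response <- 2 * df$x + rnorm(n, 0, 0.01)
  ens <- pairwise_loess_ensemble(df, "x", n_sub = 1000, n_reps = 30,
                                 seed = 3)
  sel <- ens$x >= 0.05 & ens$x <= 0.95
  expect_lt(max(abs(ens$median[sel] - 2 * ens$x[sel])), 0.02)
  expect_true(all(ens$lower <= ens$median + 1e-12))
  expect_true(all(ens$median <= ens$upper + 1e-12))
  # noise-free monotone data: monotone median curve on the interior
  df2 <- data.frame(x = runif(n))
  df2$response <- df2$x^3
  ens2 <- pairwise_loess_ensemble(df2, "x", n_sub = 1000, n_reps = 10,
                                  seed = 4)
  inner <- ens2$median[ens2$x >= 0.05 & ens2$x <= 0.95]
  # local quadratic fits wiggle slightly where the truth is flat; dips
  # stay below half a percent of the curve's range
  expect_true(all(diff(inner) > -5e-3 * diff(range(inner))))
  # degenerate feature errors; oversized subsample clamps with warning
  df2$k <- 1
  expect_error(pairwise_loess_ensemble(df2, "k"), "constant")
  expect_warning(pairwise_loess_ensemble(df
    , "x", n_sub = 1e6, n_reps = 2, seed = 5), "clamped")
})

test_that("residual maps subtract with the stated sign convention", {
  g <- make_grid(c(0, 20, 0, 10), cell_km = 100)
  obs <- rw_layer(rep(1.0, n_cells(g)), g)
  pred <- rw_layer(rep(0.8, n_cells(g)), g)
  res <- residual_map(obs, pred)
  expect_true(all(abs(res$values - 0.2) < 1e-12))  # underprediction positive
  # perfect model: all-zero map
  res0 <- residual_map(obs, obs)
  expect_true(all(res0$values == 0))
  # grid mismatch rejected
  g2 <- make_grid(c(0, 20, 0, 10), cell_km = 50)
  expect_error(residual_map(obs, rw_layer(rep(1, n_cells(g2)), g2)),
               "different grids")
})

test_that("converged least-squares fits have near-zero mean training residual", {
  fit <- fitted_mid()
  expect_lt(abs(mean(residuals(fit, "train"))), 0.01)
})

test_that("zonal profiles bin, average, and recombine exactly", {
  g <- make_grid(c(0, 30, -10, 10), cell_km = 50)
  v <- runif(n_cells(g))
  zp <- zonal_profile(rw_layer(v, g), bin_deg = 2)
  expect_true(all(zp$bin_high - zp$bin_low == 2))
  # bin arithmetic on a constructed case
  rows <- g$lat >= 0 & g$lat < 2
  expect_equal(zp$mean[zp$bin_low == 0], mean(v[rows]))
  # constant layer: every occupied bin equals the constant
  zc <- zonal_profile(rw_layer(rep(3.3, n_cells(g)), g))
  expect_true(all(abs(zc$mean[!zc$empty] - 3.3) < 1e-12))
  # weighted recombination recovers the global mean exactly
  expect_equal(sum(zp$mean * zp$n_cells, na.rm = TRUE) / sum(zp$n_cells),
               mean(v))
})

test_that("semivariograms match an exhaustive-pairs oracle and detect structure", {
  g <- make_grid(c(0, 10, 0, 10), cell_km = 56)  # ~20 x 20 cells
  set.seed(71)
  white <- rnorm(n_cells(g))
  sv <- empirical_semivariogram(rw_layer(white, g))
  # exhaustive-pairs oracle computed directly
  xy <- cbind(g$x, g$y)
  dd <- as.matrix(stats::dist(xy))
  gg <- 0.5 * outer(white, white, "-")^2
  ut <- upper.tri(dd)
  edges <- seq(0, max(dd[ut]) / 2, length.out = 16)
  oracle <- vapply(seq_len(15), function(b) {
    sel <- ut & dd > edges[b] & dd <= edges[b + 1]
    if (b == 1) sel <- ut & dd >= edges[1] & dd <= edges[2]
    mean(gg[sel])
  }, numeric(1))
  expect_equal(sv$gamma, oracle, tolerance = 1e-8)
  # white noise: flat within Monte-Carlo error
  occupied <- sv$n_pairs > 100
  expect_lt(max(sv$gamma[occupied]) / min(sv$gamma[occupied]), 1.3)
  # smoothed field: gamma rises from near zero toward a sill
  set.seed(72)
  sm <- smooth_field(g, 3)$values
  svs <- empirical_semivariogram(rw_layer(sm, g))
  occ2 <- which(svs$n_pairs > 100)
  expect_lt(svs$gamma[occ2[1]], 0.2 * max(svs$gamma[occ2]))
  # constant field: gamma identically zero
  svc <- empirical_semivariogram(rw_layer(rep(2, n_cells(g)), g))
  expect_true(all(svc$gamma[svc$n_pairs > 0] == 0))
})

test_that("pair subsampling approximates the exhaustive semivariogram", {
  g <- make_grid(c(0, 10, 0, 10), cell_km = 56)
  set.seed(73)
  v <- smooth_field(g, 2)$values
  full <- empirical_semivariogram(rw_layer(v, g))
  sub <- empirical_semivariogram(rw_layer(v, g), exhaustive_below = 2,
                                 max_pairs = 2e5, seed = 9,
                                 lag_edges = c(full$lag_low,
                                               full$lag_high[15]))
  keep <- full$n_pairs > 200 & sub$n_pairs > 200
  expect_equal(sub$gamma[keep], full$gamma[keep], tolerance = 0.1)
})
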