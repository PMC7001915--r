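test_that("driver fields are reproducible and spatially autocorrelated", {
  g <- make_grid(c(0, 30, -15, 15), cell_km = 100)
  cfg <- world_config(seed = 7, n_years = 5, correlation_length = 3)
  d1 <- simulate_driver_fields(g, cfg)
  d2 <- simulate_driver_fields(g, cfg)
  expect_identical(d1$static$driver01$values, d2$static$driver01$values)
  expect_identical(d1$monthly$temperature$values,
                   d2$monthly$temperature$values)

  # Moran-type lag-1 statistic beats an independently shuffled copy
  moran_lag1 <- function(v, grid) {
    m <- matrix(v, grid$n_rows, grid$n_cols, byrow = TRUE)
    c1 <- stats::cor(as.numeric(m[, -1]), as.numeric(m[, -ncol(m)]))
    c2 <- stats::cor(as.numeric(m[-1, ]), as.numeric(m[-nrow(m), ]))
    (c1 + c2) / 2
  }
  obs <- moran_lag1(d1$static$driver01$values, g)
  set.seed(42)
  null <- replicate(20, moran_lag1(sample(d1$static$driver01$values), g))
  expect_gt(obs, max(null))
})

test_that("invalid correlation length is rejected", {
  g <- make_grid(c(0, 10, 0, 10), cell_km = 100)
  expect_error(smooth_field(g, 0), "correlation_length")
  expect_error(world_config(correlation_length = -1), "correlation_length")
})

test_that("monthly series with a single annual component is a pure sinusoid", {
  g <- make_grid(c(0, 10, 0, 10), cell_km = 100)
  cfg <- world_config(seed = 3, n_years = 5, series_noise_sd = 0,
                      seasonal_amplitudes = list(temperature = c(1, 0)))
  d <- simulate_driver_fields(g, cfg)
  x <- d$monthly$temperature$values[5, ]
  # residual after removing mean and the 12-month harmonic is zero
  t_idx <- seq_along(x)
  fit <- stats::lm(x ~ cos(2 * pi * t_idx / 12) + sin(2 * pi * t_idx / 12))
  expect_lt(max(abs(stats::residuals(fit))), 1e-8)
})

test_that("explicit full-domain niche occupies every non-excluded cell", {
  w <- tiny_world()
  occ <- range_from_niche(w$drivers, w$grid, thermal = c(-Inf, Inf),
                          latitudinal = c(-90, 90))
  expect_setequal(occ, domain_cells(w$grid, "all"))
})

test_that("nested niche intervals give nested, shrinking ranges", {
  w <- tiny_world()
  tm <- series_mean_layer(w$drivers, "temperature")$values
  ctr <- stats::median(tm, na.rm = TRUE)
  widths <- c(8, 4, 2, 1)
  ranges <- lapply(widths, function(h)
    range_from_niche(w$drivers, w$grid, thermal = ctr + c(-h, h),
                     latitudinal = c(-90, 90)))
  for (i in seq_len(length(ranges) - 1)) {
    expect_true(all(ranges[[i + 1]] %in% ranges[[i]]))
    expect_lte(length(ranges[[i + 1]]), length(ranges[[i]]))
  }
})

test_that("species range generation is reproducible under one seed", {
  w <- tiny_world()
  cfg <- w$config
  r1 <- simulate_species_ranges(w$drivers, cfg, w$grid)
  r2 <- simulate_species_ranges(w$drivers, cfg, w$grid)
  expect_identical(lengths(r1$species), lengths(r2$species))
  expect_identical(r1$species, r2$species)
})

test_that("range stacking counts covering species exactly", {
  w <- tiny_world()
  # manual ranges: three species sharing one cell, plus disjoint remainder
  cells <- domain_cells(w$grid, "all")
  ranges <- structure(list(
    species = list(cells[1:3], cells[c(1, 4)], cells[1]),
    niches = data.frame(), grid = w$grid), class = "rw_ranges")
  rich <- stack_ranges_to_richness(ranges)
  expect_equal(rich$values[cells[1]], 3)
  expect_equal(sum(rich$values), sum(lengths(ranges$species)))
  # zero species: all-zero layer
  empty <- structure(list(species = list(), niches = data.frame(),
                          grid = w$grid), class = "rw_ranges")
  expect_true(all(stack_ranges_to_richness(empty)$values == 0))
})

test_that("occurrences are confined to ranges and reproducible", {
  w <- tiny_world()
  occ1 <- simulate_occurrences(w$ranges, w$drivers, w$config, seed = 9)
  occ2 <- simulate_occurrences(w$ranges, w$drivers, w$config, seed = 9)
  expect_identical(occ1, occ2)
  for (sp in unique(occ1$species_id)) {
    rows <- occ1$species_id == sp
    expect_true(all(occ1$cell_id[rows] %in% w$ranges$species[[sp]]))
  }
  # record counts within the configured span
  counts <- table(occ1$species_id)
  expect_true(all(counts >= 1 & counts <= 1000))
})

test_that("a single-cell species carries one thermal value on all records", {
  w <- tiny_world()
  cells <- domain_cells(w$grid, "all")
  one_cell <- structure(list(species = list(cells[7]),
                             niches = data.frame(), grid = w$grid),
                        class = "rw_ranges")
  cfg <- w$config
  cfg$records_per_species <- c(50, 50)
  occ <- simulate_occurrences(one_cell, w$drivers, cfg, seed = 4)
  expect_length(unique(occ$thermal_value), 1)
})

test_that("sampled latitudinal interval converges on the range interval", {
  w <- tiny_world()
  # one wide-latitude species, many records
  lat_cells <- domain_cells(w$grid, "all")
  wide <- structure(list(species = list(lat_cells),
                         niches = data.frame(), grid = w$grid),
                    class = "rw_ranges")
  cfg <- w$config
  errs <- vapply(c(50, 1000), function(n) {
    cfg$records_per_species <- c(n, n)
    occ <- simulate_occurrences(wide, w$drivers, cfg, seed = 11)
    s <- percentile_interval(occ$lat)
    g <- percentile_interval(w$grid$lat[lat_cells])
    abs(s[1] - g[1]) + abs(s[2] - g[2])
  }, numeric(1))
  expect_lt(errs[2], errs[1])  # Monte-Carlo convergence with n
})

test_that("species with an empty range cannot yield occurrences", {
  w <- tiny_world()
  bad <- structure(list(species = list(integer(0)), niches = data.frame(),
                        grid = w$grid), class = "rw_ranges")
  expect_error(simulate_occurrences(bad, w$drivers, w$config), "empty range")
})

test_that("constant richness function returns the constant", {
  w <- tiny_world()
  cfg <- w$config
  cfg$noise_sd <- 0
  cfg$richness_function <- list(
    terms = list(list(driver = "driver01", fun = function(x) rep(7, length(x)))),
    interactions = list())
  r <- true_richness_function(w$drivers, cfg)
  expect_true(all(r$values == 7))
})

test_that("additive richness function matches direct per-cell evaluation", {
  w <- tiny_world()
  cfg <- w$config
  cfg$noise_sd <- 0
  f1 <- function(x) 3 * x
  f2 <- function(x) x^2
  f3 <- function(x) exp(x)
  cfg$richness_function <- list(
    terms = list(list(driver = "driver01", fun = f1),
                 list(driver = "driver02", fun = f2),
                 list(driver = "driver03", fun = f3)),
    interactions = list())
  r <- true_richness_function(w$drivers, cfg)
  # brute-force formula evaluation cell by cell
  expected <- vapply(seq_len(n_cells(w$grid)), function(i)
    f1(w$drivers$static$driver01$values[i]) +
      f2(w$drivers$static$driver02$values[i]) +
      f3(w$drivers$static$driver03$values[i]), numeric(1))
  expect_equal(r$values, expected, tolerance = 1e-12)
})

test_that("unknown driver in the richness function errors", {
  w <- tiny_world()
  cfg <- w$config
  cfg$richness_function <- list(
    terms = list(list(driver = "driver99", fun = identity)),
    interactions = list())
  expect_error(true_richness_function(w$drivers, cfg), "driver99")
})

test_that("response-scale noise has the configured standard deviation", {
  cfg <- world_config(seed = 77, noise_sd = 0.1, n_years = 5, n_species = 5)
  w <- simulate_world(cfg, extent = c(-35, 35, -28, 28), cell_km = 55)
  expect_gte(n_cells(w$grid), 1e4)
  eps <- log1p(w$richness$values) - log1p(w$richness_true$values)
  expect_equal(sd(eps), 0.1, tolerance = 0.03)
  expect_equal(mean(eps), 0, tolerance = 0.01)
})

test_that("default world has the expected statistical shape", {
  w <- tiny_world()
  rich <- w$richness$values
  expect_true(all(rich >= 0))
  # right-skew: mean above median
  expect_gt(mean(rich), stats::median(rich))
  tab <- feature_table_of(w)
  feats <- as.matrix(tab[, attr(tab, "feature_names")])
  expect_true(all(feats >= 0 & feats <= 1))
})
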