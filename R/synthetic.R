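#' Synthetic worlds with known driver-richness structure
#'
#' The generator produces everything the real pipeline consumes — an
#' equal-area grid, spatially autocorrelated environmental driver fields
#' (some as monthly time series with 12- and 6-month seasonal components),
#' niche-derived species ranges, point occurrence records, and a richness
#' surface — from a single seeded configuration, so every downstream stage
#' can be tested against known truth.
#'
#' @name synthetic_world
NULL

#' Configuration of a synthetic world
#'
#' @param seed integer; fully determines all generator outputs.
#' @param n_species number of species ranges to draw.
#' @param n_true_drivers number of static driver fields that enter the true
#'   richness function.
#' @param n_distractor_drivers static driver fields with no causal effect.
#' @param correlation_length spatial correlation length of driver fields,
#'   in cells (Gaussian kernel sd).
#' @param seasonal_amplitudes named list of `c(a12, a6)` amplitudes for each
#'   monthly series (12-month and 6-month components).
#' @param series_noise_sd white-noise sd added to every monthly series.
#' @param noise_sd sd of Gaussian noise added to richness on the ln(x+1)
#'   (response) scale.
#' @param n_years length of the monthly series in years.
#' @param land_fraction fraction of cells assigned to the land domain.
#' @param records_per_species range `c(min, max)` of the log-uniform
#'   per-species record-count distribution.
#' @param niche_breadth `c(thermal_sd, latitudinal_sd)` scales (degrees C /
#'   degrees latitude) from which species niche half-widths are drawn.
#' @param retry_cap redraw attempts before an empty species range errors.
#' @param richness_function list with element `terms`, each term a list
#'   `list(driver = "driver01", fun = function(x) ...)`, and optionally
#'   `interactions`, each `list(drivers = c(a, b), fun = function(x, y)
#'   ...)`. Evaluated on the (0-1 scaled) static driver layers; its value is
#'   the noiseless richness. `NULL` gives the default 3-term additive
#'   function (Gaussian bump, linear and quadratic components) over the
#'   first three true drivers.
#' @return an object of class `rw_world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_species = 200L,
                         n_true_drivers = 3L,
                         n_distractor_drivers = 27L,
                         correlation_length = 5,
                         seasonal_amplitudes = list(
                           temperature = c(8, 1),
                           production  = c(1, 0.5),
                           insolation  = c(60, 10)),
                         series_noise_sd = 0.1,
                         noise_sd = 0.05,
                         n_years = 10L,
                         land_fraction = 0.3,
                         records_per_species = c(1, 1000),
                         niche_breadth = c(4, 12),
                         retry_cap = 50L,
                         richness_function = NULL) {
  if (n_true_drivers < 1) stop("`n_true_drivers` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (correlation_length <= 0) stop("`correlation_length` must be > 0")
  if (n_years < 1) stop("`n_years` must be >= 1")
  if (records_per_species[1] < 1 || records_per_species[2] <
      records_per_species[1])
    stop("`records_per_species` must be c(min, max) with 1 <= min <= max")
  cfg <- structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    n_true_drivers = as.integer(n_true_drivers),
    n_distractor_drivers = as.integer(n_distractor_drivers),
    correlation_length = correlation_length,
    seasonal_amplitudes = seasonal_amplitudes,
    series_noise_sd = series_noise_sd,
    noise_sd = noise_sd, n_years = as.integer(n_years),
    land_fraction = land_fraction,
    records_per_species = records_per_species,
    niche_breadth = niche_breadth,
    retry_cap = as.integer(retry_cap),
    richness_function = richness_function
  ), class = "rw_world_config")
  if (is.null(cfg$richness_function))
    cfg$richness_function <- default_richness_function(cfg)
  cfg
}

#' Default true richness function
#'
#' Three components with distinct, smooth shapes over the first three true
#' drivers (all scaled 0-1) — a Gaussian optimum, a linear ramp and a
#' quadratic ramp — additive on the ln(x+1) scale: richness =
#' expm1(2 * (g1 + g2 + g3)). Multiplicative filtering on the richness
#' scale is the ecologically natural form (each driver independently
#' scales suitability), makes the modelled ln-response exactly additive in
#' the components, and yields a right-skewed richness surface spanning
#' roughly 0-400.
#'
#' @param config an `rw_world_config`
#' @export
default_richness_function <- function(config) {
  shapes <- list(
    function(x) exp(-(x - 0.6)^2 / (2 * 0.18^2)),
    function(x) x,
    function(x) x^2
  )
  k <- min(3L, config$n_true_drivers)
  terms <- lapply(seq_len(k), function(i)
    list(driver = sprintf("driver%02d", i), fun = shapes[[i]]))
  list(terms = terms, interactions = list(),
       transform = function(s) expm1(2 * s))
}

# driver naming convention: driver01..driverNN (true drivers first)
driver_names <- function(config) {
  n <- config$n_true_drivers + config$n_distractor_drivers
  sprintf("driver%02d", seq_len(n))
}

#' Spatially autocorrelated random field
#'
#' Gaussian-kernel smoothing of white noise: the kernel sd (in cells) sets
#' the correlation length. Edge weights are renormalised so the field is
#' stationary in mean near the borders. Output is rescaled to [0, 1].
#'
#' @param grid an `rw_grid`
#' @param correlation_length kernel sd in cells (> 0)
#' @param rescale if TRUE (default) affinely rescale to [0, 1]
#' @return an `rw_layer`
#' @export
smooth_field <- function(grid, correlation_length, rescale = TRUE) {
  stopifnot(inherits(grid, "rw_grid"))
  if (correlation_length <= 0) stop("`correlation_length` must be > 0")
  m <- matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols)
  sm <- .gauss_smooth(m, correlation_length)
  v <- as.numeric(t(sm))  # back to row-major cell order
  if (rescale) {
    r <- range(v)
    if (r[1] < r[2]) v <- (v - r[1]) / (r[2] - r[1])
  }
  rw_layer(v, grid)
}

# separable truncated-Gaussian smoothing with edge renormalisation
.gauss_smooth <- function(m, sd_cells) {
  sm1 <- function(mat, sd) {
    n <- nrow(mat)
    hw <- max(1L, ceiling(3 * sd))
    d <- outer(seq_len(n), seq_len(n), function(i, j) i - j)
    K <- exp(-d^2 / (2 * sd^2))
    K[abs(d) > hw] <- 0
    K <- K / rowSums(K)
    K %*% mat
  }
  t(sm1(t(sm1(m, sd_cells)), sd_cells))
}

#' Simulate the environmental driver fields of a world
#'
#' Static layers: `n_true + n_distractor` spatially autocorrelated fields
#' (`driver01`, `driver02`, ...) scaled 0-1, plus an `elevation` field.
#' Monthly series: `temperature` (with a latitudinal mean gradient),
#' `production` and `insolation`, each the cell's baseline plus 12-month
#' and 6-month sinusoids with configured amplitudes, independent random
#' phase per cell, and white noise.
#'
#' @param grid an `rw_grid`
#' @param config an `rw_world_config`
#' @return a list of class `rw_drivers`: `static` (named `rw_layer`s),
#'   `monthly` (named `rw_series`), and `grid`.
#' @export
simulate_driver_fields <- function(grid, config) {
  stopifnot(inherits(grid, "rw_grid"), inherits(config, "rw_world_config"))
  if (config$correlation_length <= 0)
    stop("`correlation_length` must be > 0")
  set.seed(config$seed)
  nc <- n_cells(grid)
  n_months <- 12L * config$n_years

  static <- list()
  for (nm in driver_names(config)) {
    static[[nm]] <- smooth_field(grid, config$correlation_length)
    static[[nm]]$name <- nm
  }
  elev <- smooth_field(grid, config$correlation_length)
  elev$values <- (elev$values - 0.5) * 10000  # pseudo-metres
  elev$name <- "elevation"
  static$elevation <- elev

  monthly <- list()
  t_idx <- seq_len(n_months)
  for (nm in names(config$seasonal_amplitudes)) {
    amp <- config$seasonal_amplitudes[[nm]]
    base <- smooth_field(grid, config$correlation_length)$values
    mean_level <- switch(nm,
      temperature = 30 - 0.45 * abs(grid$lat) + 4 * (base - 0.5),
      production  = 2 + 3 * base,
      insolation  = 250 - 1.5 * abs(grid$lat) + 40 * (base - 0.5),
      10 * base)
    ph12 <- stats::runif(nc, 0, 12)
    ph6 <- stats::runif(nc, 0, 6)
    s12 <- amp[1] * cos(2 * pi * outer(ph12, t_idx, function(p, t) (t - p)) / 12)
    s6 <- if (length(amp) > 1 && amp[2] != 0)
      amp[2] * cos(2 * pi * outer(ph6, t_idx, function(p, t) (t - p)) / 6)
    else 0
    noise <- if (config$series_noise_sd > 0)
      matrix(stats::rnorm(nc * n_months, 0, config$series_noise_sd),
             nc, n_months)
    else 0
    monthly[[nm]] <- rw_series(mean_level + s12 + s6 + noise, grid, nm)
  }

  structure(list(static = static, monthly = monthly, grid = grid),
            class = "rw_drivers")
}

#' @export
print.rw_drivers <- function(x, ...) {
  cat(sprintf("<rw_drivers> %d static layers, %d monthly series on %dx%d grid\n",
              length(x$static), length(x$monthly),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Per-cell mean of a monthly series
#' @param drivers an `rw_drivers`
#' @param name series name (e.g. `"temperature"`)
#' @return an `rw_layer`
#' @export
series_mean_layer <- function(drivers, name) {
  s <- drivers$monthly[[name]]
  if (is.null(s)) stop("no monthly series named '", name, "'")
  rw_layer(rowMeans(s$values), drivers$grid, paste0(name, "_mean"))
}

#' Species range from explicit niche intervals
#'
#' Occupied cells are the non-excluded cells (of the requested domain) whose
#' mean temperature lies in `thermal` and whose latitude lies in `latitudinal`.
#'
#' @param drivers an `rw_drivers`
#' @param grid grid carrying the domain mask
#' @param thermal `c(low, high)` interval on cell mean temperature
#' @param latitudinal `c(low, high)` interval on cell latitude (degrees)
#' @param domain `"all"`, `"land"` or `"ocean"`
#' @return integer vector of occupied cell ids
#' @export
range_from_niche <- function(drivers, grid, thermal, latitudinal,
                             domain = "all") {
  tm <- series_mean_layer(drivers, "temperature")$values
  cand <- domain_cells(grid, domain)
  cand[tm[cand] >= thermal[1] & tm[cand] <= thermal[2] &
         grid$lat[cand] >= latitudinal[1] & grid$lat[cand] <= latitudinal[2]]
}

#' Simulate species ranges from environmental niches
#'
#' Each species draws a niche centre at a random non-excluded cell and
#' thermal / latitudinal half-widths (folded-normal with scales
#' `config$niche_breadth`); its range is every cell of its domain whose mean
#' temperature and latitude fall inside both intervals. Species alternate
#' between ocean and land domains in proportion to cell counts. Empty
#' ranges are redrawn up to `config$retry_cap` times.
#'
#' @param drivers an `rw_drivers`
#' @param config an `rw_world_config`
#' @param grid optional grid with domain mask (defaults to the drivers' grid)
#' @return object of class `rw_ranges`: list with `species` (list of cell-id
#'   vectors), `niches` (data.frame) and `grid`.
#' @export
simulate_species_ranges <- function(drivers, config, grid = drivers$grid) {
  stopifnot(inherits(drivers, "rw_drivers"),
            inherits(config, "rw_world_config"))
  set.seed(config$seed + 1L)
  tm <- series_mean_layer(drivers, "temperature")$values
  doms <- c("ocean", "land")
  dom_cells <- lapply(doms, function(d) domain_cells(grid, d))
  names(dom_cells) <- doms
  w <- vapply(dom_cells, length, 0L)
  if (all(w == 0)) stop("grid has no non-excluded cells")
  doms <- doms[w > 0]; w <- w[w > 0]

  species <- vector("list", config$n_species)
  niches <- data.frame(species_id = seq_len(config$n_species),
                       domain = NA_character_, t_lo = NA_real_,
                       t_hi = NA_real_, lat_lo = NA_real_,
                       lat_hi = NA_real_)
  for (i in seq_len(config$n_species)) {
    dom <- sample(doms, 1, prob = w)
    cells <- dom_cells[[dom]]
    found <- FALSE
    for (try in seq_len(config$retry_cap)) {
      ctr <- sample(cells, 1)
      t_hw <- abs(stats::rnorm(1, 0, config$niche_breadth[1])) + 0.5
      l_hw <- abs(stats::rnorm(1, 0, config$niche_breadth[2])) + 1
      t_int <- tm[ctr] + c(-1, 1) * t_hw
      l_int <- grid$lat[ctr] + c(-1, 1) * l_hw
      occ <- cells[tm[cells] >= t_int[1] & tm[cells] <= t_int[2] &
                     grid$lat[cells] >= l_int[1] & grid$lat[cells] <= l_int[2]]
      if (length(occ) > 0) {
        species[[i]] <- occ
        niches[i, 2:6] <- list(dom, t_int[1], t_int[2], l_int[1], l_int[2])
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("could not generate a non-empty range for species ", i,
           " after ", config$retry_cap, " attempts")
  }
  structure(list(species = species, niches = niches, grid = grid),
            class = "rw_ranges")
}

#' @export
print.rw_ranges <- function(x, ...) {
  sz <- lengths(x$species)
  cat(sprintf("<rw_ranges> %d species; range size median %d [%d, %d] cells\n",
              length(x$species), as.integer(stats::median(sz)),
              min(sz), max(sz)))
  invisible(x)
}

#' Stack species ranges into a richness surface
#'
#' Cell value = number of species whose range contains the cell (the
#' overlaid-range-map richness construction).
#'
#' @param ranges an `rw_ranges`
#' @param grid the grid (defaults to the ranges' grid)
#' @param species optional integer subset of species to stack
#' @return an `rw_layer` of integer counts
#' @export
stack_ranges_to_richness <- function(ranges, grid = ranges$grid,
                                     species = NULL) {
  stopifnot(inherits(ranges, "rw_ranges"))
  sp <- if (is.null(species)) ranges$species else ranges$species[species]
  occ <- as.integer(unlist(sp, use.names = FALSE))
  counts <- tabulate(occ, nbins = n_cells(grid))
  rw_layer(counts, grid, "richness")
}

#' Simulate point occurrence records
#'
#' Per-species record counts are drawn log-uniformly over
#' `config$records_per_species`; each record picks a uniform cell of the
#' species' range, is jittered uniformly within the cell, gets a random
#' month index, and carries the cell's mean temperature as its thermal
#' value.
#'
#' @param ranges an `rw_ranges`
#' @param drivers an `rw_drivers` (for the temperature series)
#' @param config an `rw_world_config`
#' @param seed integer seed (defaults to `config$seed + 2`)
#' @return data.frame of class `rw_occurrences` with columns `species_id`,
#'   `lon`, `lat`, `month_index`, `thermal_value`, `cell_id`.
#' @export
simulate_occurrences <- function(ranges, drivers, config,
                                 seed = config$seed + 2L) {
  stopifnot(inherits(ranges, "rw_ranges"), inherits(drivers, "rw_drivers"))
  set.seed(seed)
  grid <- ranges$grid
  tm <- series_mean_layer(drivers, "temperature")$values
  n_months <- ncol(drivers$monthly$temperature$values)
  rng <- config$records_per_species
  n_sp <- length(ranges$species)
  n_rec <- pmin(rng[2], pmax(rng[1], round(exp(
    stats::runif(n_sp, log(rng[1]), log(rng[2]))))))

  out <- vector("list", n_sp)
  R <- .EARTH_RADIUS_KM
  half <- grid$cell_km / 2
  for (i in seq_len(n_sp)) {
    occ <- ranges$species[[i]]
    if (length(occ) == 0) stop("species ", i, " has an empty range")
    cells <- occ[sample.int(length(occ), n_rec[i], replace = TRUE)]
    x <- grid$x[cells] + stats::runif(n_rec[i], -half, half)
    y <- grid$y[cells] + stats::runif(n_rec[i], -half, half)
    out[[i]] <- data.frame(
      species_id = i,
      lon = x / R * 180 / pi,
      lat = asin(pmin(1, pmax(-1, y / R))) * 180 / pi,
      month_index = sample.int(n_months, n_rec[i], replace = TRUE),
      thermal_value = tm[cells],
      cell_id = cells
    )
  }
  occ <- do.call(rbind, out)
  class(occ) <- c("rw_occurrences", "data.frame")
  occ
}

#' Evaluate the true driver-richness function
#'
#' The configured function is evaluated per cell on the static driver
#' layers: the sum of its `terms` (and `interactions`), passed through its
#' `transform` if one is set (the default world uses
#' `transform = function(s) expm1(2 s)`, making the ln(x+1) response
#' additive in the components). Gaussian noise with sd `config$noise_sd`
#' is then added on the ln(x+1) scale (`value = expm1(log1p(f) + eps)`,
#' clamped at 0), so the modelled response carries additive noise of
#' exactly that sd. With `noiseless = TRUE` (or `noise_sd = 0`) the exact
#' function value is returned.
#'
#' @param drivers an `rw_drivers`
#' @param config an `rw_world_config`
#' @param noiseless return the exact function value without noise
#' @param seed seed for the noise draw (defaults to `config$seed + 3`)
#' @return an `rw_layer`
#' @export
true_richness_function <- function(drivers, config, noiseless = FALSE,
                                   seed = config$seed + 3L) {
  stopifnot(inherits(drivers, "rw_drivers"),
            inherits(config, "rw_world_config"))
  rf <- config$richness_function
  nc <- n_cells(drivers$grid)
  f <- numeric(nc)
  get_layer <- function(nm) {
    if (is.null(drivers$static[[nm]]))
      stop("richness function references unknown driver '", nm, "'")
    drivers$static[[nm]]$values
  }
  for (tm in rf$terms) f <- f + tm$fun(get_layer(tm$driver))
  for (ia in rf$interactions)
    f <- f + ia$fun(get_layer(ia$drivers[1]), get_layer(ia$drivers[2]))
  if (!is.null(rf$transform)) f <- rf$transform(f)
  if (noiseless || config$noise_sd == 0)
    return(rw_layer(f, drivers$grid, "true_richness"))
  set.seed(seed)
  v <- pmax(0, expm1(log1p(f) + stats::rnorm(nc, 0, config$noise_sd)))
  rw_layer(v, drivers$grid, "richness")
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: grid, drivers, land/ocean domains, species ranges,
#' stacked richness, function-based richness and occurrence records, all
#' from one seeded config.
#'
#' @param config an `rw_world_config`
#' @param extent,cell_km grid geometry (see [make_grid()])
#' @param richness `"function"` (known driver-richness function; the
#'   default) or `"ranges"` (stacked species ranges)
#' @return list of class `rw_world` with elements `grid`, `drivers`,
#'   `ranges`, `richness`, `richness_true` (noiseless), `occurrences`,
#'   `config`.
#' @export
simulate_world <- function(config = world_config(),
                           extent = c(-180, 180, -60, 60),
                           cell_km = 50,
                           richness = c("function", "ranges")) {
  richness <- match.arg(richness)
  grid <- make_grid(extent, cell_km)
  drivers <- simulate_driver_fields(grid, config)
  grid <- assign_domains(grid, drivers$static$elevation,
                         config$land_fraction)
  drivers$grid <- grid
  for (nm in names(drivers$static)) drivers$static[[nm]]$grid <- grid
  for (nm in names(drivers$monthly)) drivers$monthly[[nm]]$grid <- grid
  ranges <- simulate_species_ranges(drivers, config, grid)
  occ <- simulate_occurrences(ranges, drivers, config)
  rich <- switch(richness,
    "function" = true_richness_function(drivers, config),
    "ranges" = stack_ranges_to_richness(ranges, grid))
  rich_true <- if (richness == "function")
    true_richness_function(drivers, config, noiseless = TRUE)
  else rich
  structure(list(grid = grid, drivers = drivers, ranges = ranges,
                 richness = rich, richness_true = rich_true,
                 occurrences = occ, config = config),
            class = "rw_world")
}

#' @export
print.rw_world <- function(x, ...) {
  cat("<rw_world>\n")
  print(x$grid)
  print(x$drivers)
  print(x$ranges)
  cat(sprintf("  %d occurrence records\n", nrow(x$occurrences)))
  invisible(x)
}
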