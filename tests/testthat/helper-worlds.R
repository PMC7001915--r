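# Shared fixtures: small seeded worlds built once per test run.

# tiny world: ~600 cells, 5 static drivers + series, fast to generate
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- world_config(seed = 101, n_species = 15, n_true_drivers = 3,
                          n_distractor_drivers = 2, n_years = 5,
                          records_per_species = c(5, 200))
      cache <<- simulate_world(cfg, extent = c(0, 25, -12, 12),
                               cell_km = 100)
    }
    cache
  }
})

# mid-size world for model tests: ~3000 cells, 30 drivers, noiseless
mid_world_noiseless <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- world_config(seed = 202, n_species = 10, noise_sd = 0,
                          n_years = 5)
      cache <<- simulate_world(cfg, extent = c(-20, 20, -18, 18),
                               cell_km = 75)
    }
    cache
  }
})

feature_table_of <- function(world, n_drivers = NULL, domain = "all") {
  nm <- sprintf("driver%02d", seq_len(
    if (is.null(n_drivers))
      world$config$n_true_drivers + world$config$n_distractor_drivers
    else n_drivers))
  build_feature_table(world$drivers$static[nm], world$richness,
                      world$grid, domain = domain)
}

# independent type-7 percentile oracle built on stats::quantile
quantile_oracle <- function(x, probs) {
  stats::quantile(x, probs, type = 7, names = FALSE)
}
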