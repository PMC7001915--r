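test_that("percentile intervals follow the linear-interpolation convention", {
  # constant input: zero-width interval
  pi0 <- percentile_interval(c(5, 5, 5))
  expect_equal(as.numeric(pi0), c(5, 5))
  expect_equal(attr(pi0, "width"), 0)
  # 0..100 inclusive: 1st and 99th percentiles are exactly 1 and 99
  pi1 <- percentile_interval(0:100)
  expect_equal(as.numeric(pi1), c(1, 99))
  # extreme percentiles give min and max
  x <- rnorm(57)
  pi2 <- percentile_interval(x, 0, 100)
  expect_equal(as.numeric(pi2), range(x))
  # matches stats::quantile type 7 on irregular data
  set.seed(8)
  y <- rexp(83)
  expect_equal(as.numeric(percentile_interval(y, 3, 87)),
               quantile_oracle(y, c(0.03, 0.87)))
  expect_error(percentile_interval(numeric(0)), "at least one")
})

test_that("resampled range widths behave at the degenerate and exhaustive limits", {
  expect_true(all(resample_range_widths(rep(3, 40), n = 10, reps = 50,
                                        seed = 1) == 0))
  x <- runif(60, -20, 20)
  w_full <- resample_range_widths(x, n = 60, reps = 20, seed = 2)
  expect_true(all(abs(w_full - attr(percentile_interval(x), "width")) < 1e-12))
  expect_error(resample_range_widths(x, n = 61), "exceeds")
  expect_error(resample_range_widths(x, n = 1), "> 1")
})

test_that("median resampled width increases stochastically with n", {
  set.seed(3)
  x <- runif(500, -30, 30)
  med_w <- vapply(c(5, 20, 80, 320), function(n)
    stats::median(resample_range_widths(x, n, reps = 500, seed = 4)),
    numeric(1))
  expect_true(all(diff(med_w) > 0))
})

test_that("identical records give minimum sufficient count of 2", {
  expect_equal(min_sufficient_records(rep(1.5, 100), reps = 200, seed = 1), 2L)
})

test_that("binary search and literal scan agree on the minimum", {
  set.seed(9)
  x <- runif(150, 0, 10)
  m_bin <- min_sufficient_records(x, reps = 500, seed = 11,
                                  method = "binary")
  m_scan <- min_sufficient_records(x, reps = 500, seed = 11,
                                   method = "scan")
  expect_lte(abs(m_bin - m_scan), 2)
})

test_that("raising required coverage never lowers the minimum", {
  set.seed(10)
  x <- runif(200, -5, 5)
  m95 <- min_sufficient_records(x, reps = 500, coverage = 0.95, seed = 3)
  m99 <- min_sufficient_records(x, reps = 500, coverage = 0.99, seed = 3)
  expect_gte(m99, m95)
})

test_that("min_sufficient_records validates its input", {
  expect_error(min_sufficient_records(c(1)), "at least 2")
})

test_that("screening filters by record count and keeps totals consistent", {
  set.seed(12)
  counts <- c(10, 40, 41, 100, 1000)
  occ <- do.call(rbind, lapply(seq_along(counts), function(i)
    data.frame(species_id = i, lon = runif(counts[i]),
               lat = runif(counts[i], -30, 30),
               month_index = 1L,
               thermal_value = runif(counts[i], 10, 25))))
  scr <- screen_species(occ, threshold = 41)
  expect_equal(sum(scr$report$passed), 3)
  expect_setequal(unique(scr$records$species_id), c(3, 4, 5))
  expect_equal(nrow(scr$records), sum(counts[3:5]))
  # vacuous filter keeps everything
  scr1 <- screen_species(occ, threshold = 1)
  expect_equal(nrow(scr1$records), nrow(occ))
  # idempotence: screening an already-screened set changes nothing
  scr2 <- screen_species(scr$records, threshold = 41)
  expect_equal(nrow(scr2$records), nrow(scr$records))
  expect_true(all(scr2$report$passed))
})

test_that("median and spread summarise min-sufficient counts", {
  expect_equal(median_min_sufficient(c(33)), c(median = 33, spread = 0))
  expect_equal(median_min_sufficient(c(30, 33, 36))[["median"]], 33)
  expect_error(median_min_sufficient(c(NA_integer_, NA_integer_)),
               "undetermined")
})

test_that("analytic rarefaction matches the hypergeometric closed form", {
  # single species: curve constant at 1
  r1 <- rarefaction_curve(rep("a", 30), c(1, 5, 30))
  expect_true(all(r1$expected_species == 1))
  # all singletons: E[S(n)] = n
  r2 <- rarefaction_curve(1:25, c(1, 10, 25))
  expect_equal(r2$expected_species, c(1, 10, 25))
  # non-decreasing and bounded by the species count
  set.seed(14)
  pool <- sample(1:40, 500, replace = TRUE, prob = rexp(40))
  sizes <- c(1, 5, 10, 50, 100, 250, 500)
  ra <- rarefaction_curve(pool, sizes)
  expect_true(all(diff(ra$expected_species) >= 0))
  expect_true(all(ra$expected_species <= 40))
  expect_error(rarefaction_curve(pool, 501), "pool size")
})

test_that("Monte-Carlo rarefaction converges to the analytic curve", {
  set.seed(15)
  pool <- sample(1:40, 500, replace = TRUE, prob = rexp(40))
  sizes <- c(5, 25, 100, 400)
  ra <- rarefaction_curve(pool, sizes, method = "analytic")
  rm <- rarefaction_curve(pool, sizes, method = "montecarlo",
                          reps = 3000, seed = 16)
  expect_equal(rm$expected_species, ra$expected_species, tolerance = 0.02)
})

test_that("analytic rarefaction agrees with vegan::rarefy", {
  skip_if_not_installed("vegan")
  set.seed(17)
  pool <- sample(letters[1:12], 200, replace = TRUE)
  counts <- as.integer(table(pool))
  sizes <- c(10, 50, 150)
  ours <- rarefaction_curve(pool, sizes)$expected_species
  theirs <- suppressWarnings(
    as.numeric(vegan::rarefy(matrix(counts, nrow = 1), sizes)))
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("latitudinal rarefaction partitions records into split-hemisphere bins", {
  set.seed(18)
  occ <- data.frame(species_id = sample(1:10, 300, TRUE),
                    lat = runif(300, -90, 90))
  lr <- latitudinal_rarefaction(occ, bin_deg = 20)
  # bins partition: record totals add up
  expect_equal(sum(vapply(lr$bins, function(b) b$n_records, 0L)), 300)
  # equator is a bin edge, so hemispheres never share a bin
  expect_true(0 %in% lr$edges)
  # boundary record falls in exactly one bin (half-open convention)
  occ2 <- data.frame(species_id = 1, lat = 20.0)
  lr2 <- latitudinal_rarefaction(occ2, bin_deg = 20)
  hits <- vapply(lr2$bins, function(b) b$n_records, 0L)
  expect_equal(sum(hits > 0), 1)
  expect_equal(lr2$bins[[which(hits > 0)]]$bin_low, 20)
  # empty bins flagged
  expect_true(any(vapply(lr2$bins, function(b) b$empty, TRUE)))
})
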