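#' Occurrence-record sufficiency screening
#'
#' Point occurrence records only support a species' inclusion when there are
#' enough of them to recover the species' latitudinal and thermal range. The
#' screening statistic resamples n records, measures the 1st-99th percentile
#' interval along an axis, and asks for the smallest n at which more than a
#' target fraction of resampled intervals recover (reach both endpoints of,
#' within a small tolerance) the interval computed from all records.
#' Species below a global record-count threshold (default 41) are removed.
#'
#' @name occurrence_screening
NULL

# type-7 (linear interpolation) quantile pair on an unsorted vector;
# avoids stats::quantile() overhead in tight resampling loops
.q_pair <- function(x, plo, phi) {
  n <- length(x)
  hlo <- (n - 1) * plo + 1
  hhi <- (n - 1) * phi + 1
  jlo <- floor(hlo); jhi <- floor(hhi)
  ks <- unique(pmin(n, c(jlo, jlo + 1, jhi, jhi + 1)))
  xs <- sort(x, partial = ks)
  lo <- xs[jlo] + (hlo - jlo) * (xs[min(n, jlo + 1)] - xs[jlo])
  hi <- xs[jhi] + (hhi - jhi) * (xs[min(n, jhi + 1)] - xs[jhi])
  c(lo, hi)
}

#' Percentile interval of a set of values
#'
#' Endpoints are the `lo`-th and `hi`-th percentiles under the
#' linear-interpolation (type 7) convention.
#'
#' @param values numeric vector (at least one value)
#' @param lo,hi percentiles in [0, 100] (defaults 1 and 99)
#' @return named numeric `c(low, high)` with attribute `width`
#' @examples
#' percentile_interval(0:100)  # c(1, 99)
#' @export
percentile_interval <- function(values, lo = 1, hi = 99) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("`values` must contain at least one finite value")
  if (lo > hi) stop("`lo` must be <= `hi`")
  q <- .q_pair(values, lo / 100, hi / 100)
  structure(c(low = q[1], high = q[2]), width = q[2] - q[1])
}

#' Resampled range widths at a fixed sample size
#'
#' Draws `reps` subsamples of `n` records (without replacement by default)
#' and returns the 1st-99th percentile width of each subsample.
#'
#' @param values numeric vector of axis values (latitudes or thermal values)
#' @param n subsample size, `1 < n <= length(values)`
#' @param reps number of resamples
#' @param lo,hi interval percentiles (defaults 1 and 99)
#' @param replace sample with replacement?
#' @param seed optional integer seed
#' @return numeric vector of `reps` widths
#' @export
resample_range_widths <- function(values, n, reps = 1000, lo = 1, hi = 99,
                                  replace = FALSE, seed = NULL) {
  values <- values[is.finite(values)]
  N <- length(values)
  if (n <= 1) stop("`n` must be > 1")
  if (!replace && n > N) stop("`n` (", n, ") exceeds number of records (", N, ")")
  if (!is.null(seed)) set.seed(seed)
  plo <- lo / 100; phi <- hi / 100
  vapply(seq_len(reps), function(r) {
    s <- values[sample.int(N, n, replace = replace)]
    q <- .q_pair(s, plo, phi)
    q[2] - q[1]
  }, numeric(1))
}

# fraction of resampled intervals that capture the global interval: the
# sample's 1st-99th percentile interval must reach to within tol * width
# of both global endpoints. Seeded per n so a directed search and a
# linear scan see identical draws at each n.
.capture_rate <- function(values, n, reps, lo_lim, hi_lim, plo, phi,
                          replace, seed) {
  if (!is.null(seed))
    set.seed((abs(seed) * 1009L + n) %% 2147483647L)
  .capture_rate_cpp(values, n, reps, lo_lim, hi_lim, plo, phi, replace)
}

#' Minimum sufficient record count along one axis
#'
#' The smallest subsample size n at which resamples of n records recover
#' the species' range: a resample succeeds when its 1st-99th percentile
#' interval reaches to within `tol` x width of both endpoints of the
#' global (all-records) 1st-99th percentile interval, and n is sufficient
#' when more than `coverage` of `reps` resamples succeed. Small samples
#' underestimate the range and fail; success probability rises to 1 at
#' n = n_records (without replacement). The default literal upward scan
#' (`method = "scan"`) returns the exact minimum; `method = "binary"` is a
#' faster bisection that assumes monotone success probability — on
#' duplicate-heavy data the percentile interpolation weight makes the
#' success curve locally sawtoothed and bisection can overshoot the first
#' crossing.
#'
#' @param values numeric vector of axis values (>= 2 records)
#' @param reps resamples per candidate n (default 1000)
#' @param coverage required success fraction, strict (default 0.95,
#'   i.e. "more than 950 of 1000")
#' @param tol endpoint tolerance as a fraction of the global interval
#'   width (default 0.1). The tolerance defines how exactly a resample
#'   must recover the range; 0.1 places the sufficiency statistic at the
#'   scale of tens of records for clustered occurrence data (near-zero
#'   tolerances would demand nearly all records for continuous values)
#' @param lo,hi interval percentiles
#' @param replace sample with replacement?
#' @param seed integer seed; per-n draws are derived from it so scan and
#'   binary search are mutually consistent
#' @param method `"scan"` (default, exact) or `"binary"` (fast,
#'   assumes monotone success probability)
#' @return the minimal sufficient n (integer), or `NA` if no n qualifies
#' @export
min_sufficient_records <- function(values, reps = 1000, coverage = 0.95,
                                   tol = 0.1, lo = 1, hi = 99,
                                   replace = FALSE, seed = NULL,
                                   method = c("scan", "binary")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  N <- length(values)
  if (N < 2) stop("need at least 2 records")
  g <- percentile_interval(values, lo, hi)
  w <- attr(g, "width")
  lo_lim <- g[1] + tol * w
  hi_lim <- g[2] - tol * w
  plo <- lo / 100; phi <- hi / 100
  success <- function(n)
    .capture_rate(values, n, reps, lo_lim, hi_lim, plo, phi, replace,
                  seed) > coverage

  if (method == "scan") {
    for (n in 2:N) if (success(n)) return(as.integer(n))
    return(NA_integer_)
  }
  if (!success(N)) return(NA_integer_)  # possible with replace = TRUE
  lo_n <- 2L; hi_n <- N
  while (lo_n < hi_n) {
    mid <- as.integer((lo_n + hi_n) %/% 2)
    if (success(mid)) hi_n <- mid else lo_n <- mid + 1L
  }
  as.integer(lo_n)
}

#' Screen species by record count and report range intervals
#'
#' Species with fewer than `threshold` records are removed. The report
#' carries, per species, the record count, the global latitudinal and
#' thermal 1st-99th percentile intervals and (optionally) the minimum
#' sufficient record count per axis.
#'
#' @param occurrences an `rw_occurrences` data.frame (or any data.frame
#'   with `species_id`, `lat`, `thermal_value` columns)
#' @param threshold minimum record count to retain a species (default 41)
#' @param compute_min_sufficient also compute per-axis minimum sufficient
#'   record counts (costly; default FALSE)
#' @param reps,coverage,seed passed to [min_sufficient_records()]
#' @return list of class `rw_screening`: `records` (retained occurrences)
#'   and `report` (one row per input species)
#' @export
screen_species <- function(occurrences, threshold = 41,
                           compute_min_sufficient = FALSE,
                           reps = 1000, coverage = 0.95, seed = NULL) {
  stopifnot(all(c("species_id", "lat", "thermal_value") %in%
                  names(occurrences)))
  sp <- split(seq_len(nrow(occurrences)), occurrences$species_id)
  ids <- names(sp)
  report <- do.call(rbind, lapply(seq_along(sp), function(i) {
    rows <- sp[[i]]
    lat <- occurrences$lat[rows]
    th <- occurrences$thermal_value[rows]
    li <- percentile_interval(lat)
    ti <- percentile_interval(th)
    data.frame(species_id = ids[i], n_records = length(rows),
               lat_low = li[1], lat_high = li[2],
               thermal_low = ti[1], thermal_high = ti[2],
               passed = length(rows) >= threshold, row.names = NULL)
  }))
  if (compute_min_sufficient) {
    ms <- function(rows, col) {
      v <- occurrences[[col]][rows]
      if (length(v) < 2) return(NA_integer_)
      min_sufficient_records(v, reps = reps, coverage = coverage,
                             seed = seed)
    }
    report$min_sufficient_lat <- vapply(sp, ms, 0L, col = "lat")
    report$min_sufficient_thermal <- vapply(sp, ms, 0L,
                                            col = "thermal_value")
  }
  keep_ids <- report$species_id[report$passed]
  records <- occurrences[occurrences$species_id %in% keep_ids, ,
                         drop = FALSE]
  class(records) <- class(occurrences)
  structure(list(records = records, report = report,
                 threshold = threshold), class = "rw_screening")
}

#' @export
print.rw_screening <- function(x, ...) {
  cat(sprintf(
    "<rw_screening> %d/%d species retained (threshold %d records); %d records kept\n",
    sum(x$report$passed), nrow(x$report), x$threshold, nrow(x$records)))
  invisible(x)
}

#' Median and spread of minimum sufficient record counts
#'
#' Summarises per-species minimum sufficient counts as the median with a
#' median-absolute-deviation spread (reported as `median (+/- spread)`).
#'
#' @param values integer vector of per-species minimum sufficient counts
#'   (NA = undetermined), or an `rw_screening` with min-sufficient columns
#' @param axis for an `rw_screening` input, `"latitudinal"` or `"thermal"`
#' @return named numeric `c(median, spread)`
#' @export
median_min_sufficient <- function(values, axis = c("latitudinal", "thermal")) {
  if (inherits(values, "rw_screening")) {
    axis <- match.arg(axis)
    col <- if (axis == "latitudinal") "min_sufficient_lat"
           else "min_sufficient_thermal"
    if (is.null(values$report[[col]]))
      stop("screening result has no min-sufficient counts; ",
           "rerun screen_species(compute_min_sufficient = TRUE)")
    values <- values$report[[col]]
  }
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("all min-sufficient counts undetermined")
  c(median = stats::median(values),
    spread = stats::mad(values, constant = 1))
}

#' Rarefaction curve of a record pool
#'
#' Expected number of distinct species in a uniform subsample of each size,
#' either by the closed-form hypergeometric formula
#' E[S(n)] = sum_i (1 - choose(N - N_i, n) / choose(N, n)) or by Monte
#' Carlo resampling.
#'
#' @param species_ids vector of species identifiers, one per record
#' @param sample_sizes integer subsample sizes (each <= pool size)
#' @param method `"analytic"` (default) or `"montecarlo"`
#' @param reps Monte Carlo resamples (default 1000)
#' @param seed optional integer seed for Monte Carlo
#' @return data.frame `sample_size`, `expected_species`
#' @export
rarefaction_curve <- function(species_ids, sample_sizes,
                              method = c("analytic", "montecarlo"),
                              reps = 1000, seed = NULL) {
  method <- match.arg(method)
  if (length(species_ids) == 0) stop("record pool is empty")
  N <- length(species_ids)
  if (any(sample_sizes < 1 | sample_sizes > N))
    stop("sample sizes must lie in [1, pool size = ", N, "]")
  counts <- as.integer(table(species_ids))
  es <- switch(method,
    analytic = vapply(sample_sizes, function(n) {
      # P(species i absent) = choose(N - N_i, n) / choose(N, n)
      p_absent <- exp(lchoose(N - counts, n) - lchoose(N, n))
      p_absent[N - counts < n] <- 0
      sum(1 - p_absent)
    }, numeric(1)),
    montecarlo = {
      if (!is.null(seed)) set.seed(seed)
      f <- factor(species_ids)
      vapply(sample_sizes, function(n) {
        mean(vapply(seq_len(reps), function(r)
          length(unique(f[sample.int(N, n)])), numeric(1)))
      }, numeric(1))
    })
  data.frame(sample_size = as.integer(sample_sizes), expected_species = es)
}

# 20-degree latitude bin edges split at the equator; the polar bins
# [-90,-80) and [80,90] are clipped to 10 degrees so hemispheres separate
.lat_bin_edges <- function(bin_deg) {
  pos <- seq(0, 90, by = bin_deg)
  if (pos[length(pos)] < 90) pos <- c(pos, 90)
  sort(unique(c(-pos, pos)))
}

#' Per-latitude-bin rarefaction curves
#'
#' Splits records into latitude bins (default 20 degrees, hemispheres
#' split at the equator; bins are half-open `[low, high)`, the northernmost
#' closed at 90) and computes a rarefaction curve per bin. Empty bins are
#' flagged.
#'
#' @param occurrences data.frame with `species_id` and `lat` columns
#' @param bin_deg bin width in degrees (default 20)
#' @param sample_sizes subsample sizes; default: 10 sizes up to each bin's
#'   pool size
#' @param method,reps,seed passed to [rarefaction_curve()]
#' @return list of class `rw_rarefaction`: per bin, `bin_low`, `bin_high`,
#'   `n_records`, `n_species`, `empty` flag and `curve` (data.frame or NULL)
#' @export
latitudinal_rarefaction <- function(occurrences, bin_deg = 20,
                                    sample_sizes = NULL,
                                    method = "analytic", reps = 1000,
                                    seed = NULL) {
  edges <- .lat_bin_edges(bin_deg)
  nb <- length(edges) - 1
  lat <- occurrences$lat
  bin <- findInterval(lat, edges, rightmost.closed = TRUE)
  bin[bin < 1 | bin > nb] <- NA
  bins <- lapply(seq_len(nb), function(b) {
    rows <- which(!is.na(bin) & bin == b)
    pool <- occurrences$species_id[rows]
    if (length(pool) == 0)
      return(list(bin_low = edges[b], bin_high = edges[b + 1],
                  n_records = 0L, n_species = 0L, empty = TRUE,
                  curve = NULL))
    ss <- if (is.null(sample_sizes))
      unique(pmax(1, round(seq(1, length(pool), length.out = 10))))
    else sample_sizes[sample_sizes <= length(pool)]
    list(bin_low = edges[b], bin_high = edges[b + 1],
         n_records = length(pool),
         n_species = length(unique(pool)), empty = FALSE,
         curve = rarefaction_curve(pool, ss, method = method,
                                   reps = reps, seed = seed))
  })
  structure(list(bins = bins, bin_deg = bin_deg, edges = edges),
            class = "rw_rarefaction")
}

#' @export
print.rw_rarefaction <- function(x, ...) {
  occ <- vapply(x$bins, function(b) !b$empty, TRUE)
  cat(sprintf("<rw_rarefaction> %d latitude bins (%g deg), %d occupied\n",
              length(x$bins), x$bin_deg, sum(occ)))
  invisible(x)
}
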