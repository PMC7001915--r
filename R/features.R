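#' Feature engineering for richness modelling
#'
#' Driver layers and monthly series become the model's feature table: per
#' cell, intra-annual (climatology) and inter-annual summaries (mean, sd,
#' range, cv), wavelet seasonal intensities, quantile truncation at the
#' 1 percent and 99 percent tails, and affine rescaling to [0, 1]. The
#' response is ln(x+1)-transformed richness, also rescaled 0-1. All
#' transform parameters are retained so predictions can be mapped back to
#' the original richness scale.
#'
#' @name phenology_features
NULL

.row_stat <- function(m, statistic) {
  switch(statistic,
    mean = rowMeans(m),
    sd = {
      mu <- rowMeans(m)
      sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
    },
    range = do.call(pmax, as.data.frame(m)) - do.call(pmin, as.data.frame(m)),
    cv = {
      mu <- rowMeans(m)
      s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
      out <- ifelse(abs(mu) < 1e-9, 0, s / mu)
      out
    },
    stop("unknown statistic '", statistic, "'"))
}

#' Summarise a monthly series into a layer
#'
#' Intra-annual scope: the statistic is computed over the 12 monthly
#' climatology values (per-cell means of each calendar month across
#' years). Inter-annual scope: over the per-year annual sums. The
#' coefficient of variation returns 0 (with a flag attribute) where the
#' mean magnitude is below 1e-9.
#'
#' @param series an `rw_series` (or cells x months matrix)
#' @param statistic one of `"mean"`, `"sd"`, `"range"`, `"cv"`
#' @param scope `"intra"` (within-year climatology) or `"inter"`
#'   (across annual sums)
#' @param grid required for bare matrix input
#' @return an `rw_layer`
#' @export
summarize_series <- function(series, statistic = c("mean", "sd", "range", "cv"),
                             scope = c("intra", "inter"), grid = NULL) {
  statistic <- match.arg(statistic)
  scope <- match.arg(scope)
  if (inherits(series, "rw_series")) {
    grid <- series$grid
    vals <- series$values
    nm <- series$name
  } else {
    if (is.null(grid)) stop("`grid` required for a bare matrix input")
    vals <- as.matrix(series)
    nm <- ""
  }
  T_len <- ncol(vals)
  if (T_len %% 12 != 0)
    stop("series length (", T_len, ") must be a multiple of 12 for scoped statistics")
  n_years <- T_len %/% 12
  agg <- if (scope == "intra") {
    # 12-column climatology: mean across years for each calendar month
    clim <- vapply(1:12, function(m)
      rowMeans(vals[, seq(m, T_len, by = 12), drop = FALSE]), numeric(nrow(vals)))
    clim
  } else {
    # per-year annual sums
    vapply(seq_len(n_years), function(y)
      rowSums(vals[, ((y - 1) * 12 + 1):(y * 12), drop = FALSE]),
      numeric(nrow(vals)))
  }
  if (scope == "inter" && n_years < 2 && statistic %in% c("sd", "cv", "range"))
    stop("inter-annual ", statistic, " needs at least 2 years")
  v <- .row_stat(agg, statistic)
  prefix <- if (scope == "intra") "sub" else "ann"
  rw_layer(v, grid, sprintf("%s_%s_%s", prefix, nm, statistic))
}

#' Truncate a layer at quantile tails
#'
#' Values below the `lo` quantile (above the `hi` quantile) are set to that
#' quantile. Quantiles are computed over finite cells only (i.e. the
#' masked domain when the layer is already domain-restricted). Constant
#' layers are returned unchanged with a message.
#'
#' @param layer an `rw_layer` (or numeric vector)
#' @param lo,hi truncation quantiles (defaults 0.01 and 0.99)
#' @return same type as input, with attribute `truncation = c(lo_val, hi_val)`
#' @export
truncate_quantiles <- function(layer, lo = 0.01, hi = 0.99) {
  is_layer <- inherits(layer, "rw_layer")
  v <- if (is_layer) layer$values else as.numeric(layer)
  fin <- is.finite(v)
  vals <- v[fin]
  if (length(unique(vals)) < 2) {
    message("layer is constant; truncation skipped")
    out <- layer
    attr(out, "truncation") <- c(NA_real_, NA_real_)
    return(out)
  }
  q <- stats::quantile(vals, c(lo, hi), type = 7, names = FALSE)
  v[fin] <- pmin(q[2], pmax(q[1], vals))
  if (is_layer) {
    layer$values <- v
    attr(layer, "truncation") <- q
    layer
  } else structure(v, truncation = q)
}

#' Rescale a layer to [0, 1]
#'
#' Affine map sending the minimum to 0 and the maximum to 1; the (min, max)
#' pair is stored so the map can be applied to new data or inverted.
#'
#' @param layer an `rw_layer` or numeric vector
#' @param from optional `c(min, max)` to apply a previously stored scaling
#' @return same type as input with attribute `scaling = c(min, max)`
#' @export
rescale_unit <- function(layer, from = NULL) {
  is_layer <- inherits(layer, "rw_layer")
  v <- if (is_layer) layer$values else as.numeric(layer)
  fin <- is.finite(v)
  r <- if (is.null(from)) range(v[fin]) else from
  if (!all(is.finite(r)) || r[1] >= r[2])
    stop("cannot rescale: layer is constant or has no finite values")
  v[fin] <- (v[fin] - r[1]) / (r[2] - r[1])
  if (!is.null(from) && any(v[fin] < 0 | v[fin] > 1))
    warning("values outside the stored scaling range map outside [0, 1]")
  if (is_layer) {
    layer$values <- v
    attr(layer, "scaling") <- r
    layer
  } else structure(v, scaling = r)
}

#' Invert a unit rescaling
#' @param values numeric in [0, 1] (or outside, for extrapolated inputs)
#' @param scaling the `c(min, max)` pair stored by [rescale_unit()]
#' @export
unscale_unit <- function(values, scaling) values * (scaling[2] - scaling[1]) + scaling[1]

#' Build the model feature table
#'
#' One row per cell of the requested domain: features are quantile-truncated
#' then rescaled 0-1 (elevation/depth-like layers listed in `no_truncate`
#' skip truncation); the response is rescaled ln(richness + 1). Transform
#' provenance (per-feature truncation quantiles and min/max, response
#' min/max) is stored as an attribute.
#'
#' @param layers named list of `rw_layer`s (or numeric vectors on the grid)
#' @param richness an `rw_layer` of non-negative richness
#' @param grid the shared grid (defaults to the richness layer's)
#' @param domain `"all"`, `"land"` or `"ocean"` — rows are this domain's cells
#' @param no_truncate character vector of layer names exempt from
#'   truncation (default `c("elevation", "depth")`)
#' @param lo,hi truncation quantiles
#' @return data.frame of class `rw_features` with columns `cell_id`, `lon`,
#'   `lat`, one column per feature, and `response`; attributes
#'   `feature_names`, `provenance`, `domain`, `grid`.
#' @export
build_feature_table <- function(layers, richness, grid = NULL,
                                domain = "all",
                                no_truncate = c("elevation", "depth"),
                                lo = 0.01, hi = 0.99) {
  if (inherits(richness, "rw_layer")) {
    if (is.null(grid)) grid <- richness$grid
    rich <- richness$values
  } else rich <- as.numeric(richness)
  if (is.null(grid)) stop("`grid` must be supplied")
  nc <- n_cells(grid)
  if (length(rich) != nc) stop("richness is not on the supplied grid")
  if (any(rich[is.finite(rich)] < 0)) stop("richness must be non-negative")
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("`layers` must be a named list")

  cells <- domain_cells(grid, domain)
  cells <- cells[is.finite(rich[cells])]
  prov <- list(features = list(), response = NULL)
  out <- data.frame(cell_id = cells, lon = grid$lon[cells],
                    lat = grid$lat[cells])
  for (nm in names(layers)) {
    lyr <- layers[[nm]]
    v <- if (inherits(lyr, "rw_layer")) lyr$values else as.numeric(lyr)
    if (length(v) != nc)
      stop("layer '", nm, "' is not on the supplied grid")
    v <- v[cells]
    trunc <- c(NA_real_, NA_real_)
    if (!(nm %in% no_truncate)) {
      v <- truncate_quantiles(v, lo, hi)
      trunc <- attr(v, "truncation")
    }
    v <- rescale_unit(as.numeric(v))
    prov$features[[nm]] <- list(truncation = as.numeric(trunc),
                                scaling = as.numeric(attr(v, "scaling")),
                                quantiles = c(lo, hi))
    out[[nm]] <- as.numeric(v)
  }
  lr <- log1p(rich[cells])
  rng <- range(lr)
  if (rng[1] >= rng[2]) {
    warning("richness response is constant; response set to all zero")
    resp <- rep(0, length(lr))
    rng <- c(rng[1], rng[1])
  } else resp <- (lr - rng[1]) / (rng[2] - rng[1])
  out$response <- resp
  prov$response <- list(transform = "log1p", scaling = as.numeric(rng))
  structure(out, feature_names = names(layers), provenance = prov,
            domain = domain, grid = grid,
            class = c("rw_features", "data.frame"))
}

#' Map scaled-response predictions back to richness
#'
#' Inverts the 0-1 rescale and the ln(x+1) transform using the provenance
#' stored in a feature table.
#'
#' @param values predictions on the scaled response
#' @param provenance the `provenance` attribute of an `rw_features` table
#'   (or the table itself)
#' @return richness on the original scale (non-negative)
#' @export
richness_from_response <- function(values, provenance) {
  if (inherits(provenance, "rw_features"))
    provenance <- attr(provenance, "provenance")
  rng <- provenance$response$scaling
  pmax(0, expm1(values * (rng[2] - rng[1]) + rng[1]))
}

#' Standard feature set for a driver collection
#'
#' Builds the default layer list for [build_feature_table()]: every static
#' driver as-is, and for each monthly series the intra- and inter-annual
#' mean/sd/range/cv plus (for the series named in `wavelet_series`) the
#' 6- and 12-month wavelet seasonal intensities.
#'
#' @param drivers an `rw_drivers`
#' @param wavelet_series series names that get wavelet intensity features
#'   (default production and insolation)
#' @param series_stats statistics for monthly series
#' @param wavelet_periods periods (months) for intensity features
#' @return named list of `rw_layer`s
#' @export
standard_feature_layers <- function(drivers,
                                    wavelet_series = c("production",
                                                       "insolation"),
                                    series_stats = c("mean", "sd", "range",
                                                     "cv"),
                                    wavelet_periods = c(6, 12)) {
  layers <- drivers$static
  for (nm in names(drivers$monthly)) {
    s <- drivers$monthly[[nm]]
    for (st in series_stats) {
      l1 <- summarize_series(s, st, "intra")
      layers[[l1$name]] <- l1
      l2 <- summarize_series(s, st, "inter")
      layers[[l2$name]] <- l2
    }
    if (nm %in% wavelet_series)
      for (p in wavelet_periods) {
        li <- seasonal_intensity(s, p)
        layers[[li$name]] <- li
      }
  }
  layers
}
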