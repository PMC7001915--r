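#' Model interrogation: importance, partial dependence, diagnostics
#'
#' A fitted network is interrogated by (i) bootstrapped noise-perturbation
#' variable importance — refit on random subsets, replace one feature with
#' resampled noise, record the drop in explained variance; (ii) partial
#' dependence curves and two-driver surfaces; (iii) resampled loess curve
#' ensembles for bivariate driver-richness relationships; (iv) residual
#' maps, 2-degree zonal profiles and empirical semivariograms of residual
#' spatial structure.
#'
#' @name driver_interpretation
NULL

#' Bootstrapped noise-perturbation variable importance
#'
#' Per replicate: draw a random subset of rows, split it 80/20, train a
#' fresh network, record the baseline test R2; then for each feature,
#' replace its column in the evaluation rows with resampled noise (the
#' feature's own values sampled with replacement by default, breaking the
#' association while preserving the marginal; `noise = "uniform"` draws
#' uniform [0, 1]) and record `delta_r2 = baseline - perturbed`.
#'
#' @param data feature table
#' @param config [ann_config()] used for each replicate's refit
#' @param n_reps bootstrap replicates (default 500)
#' @param subset_fraction fraction of rows drawn per replicate (default 0.8)
#' @param noise `"resample"` (default) or `"uniform"`
#' @param seed integer seed
#' @param features features to perturb (default: all model features)
#' @param formula model formula
#' @return object of class `rw_importance`: `reps` data.frame
#'   (`rep`, `feature`, `delta_r2`, `baseline_r2`) plus metadata
#' @export
permutation_importance <- function(data, config = ann_config(),
                                   n_reps = 500, subset_fraction = 0.8,
                                   noise = c("resample", "uniform"),
                                   seed = 1L, features = NULL,
                                   formula = response ~ .) {
  noise <- match.arg(noise)
  xy <- .design_matrix(formula, data)
  X <- xy$X; y <- xy$y
  n <- nrow(X)
  if (is.null(features)) features <- colnames(X)
  n_sub <- max(2, round(n * subset_fraction))
  if (floor(n_sub * 0.8) < 2)
    stop("subset too small to train: ", n_sub, " rows")
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- (abs(seed) * 2654435761 + r) %% 2147483647
    set.seed(rep_seed)
    rows <- sample.int(n, n_sub)
    n_tr <- floor(length(rows) * 0.8)
    tr <- rows[seq_len(n_tr)]
    te <- rows[(n_tr + 1):length(rows)]
    cfg <- config
    cfg$seed <- as.integer(rep_seed %% 1e9)
    fit <- .mlp_train(X[tr, , drop = FALSE], y[tr], cfg)
    Xte <- X[te, , drop = FALSE]
    yte <- y[te]
    sst <- sum((yte - mean(yte))^2)
    base_pred <- .mlp_forward(fit$weights, Xte)
    base_r2 <- 1 - sum((yte - base_pred)^2) / sst
    d <- vapply(features, function(f) {
      Xp <- Xte
      Xp[, f] <- if (noise == "resample")
        X[sample.int(n, nrow(Xp), replace = TRUE), f]
      else stats::runif(nrow(Xp))
      pr <- .mlp_forward(fit$weights, Xp)
      base_r2 - (1 - sum((yte - pr)^2) / sst)
    }, numeric(1))
    out[[r]] <- data.frame(rep = r, feature = features, delta_r2 = d,
                           baseline_r2 = base_r2, row.names = NULL)
  }
  structure(list(reps = do.call(rbind, out), n_reps = n_reps,
                 subset_fraction = subset_fraction, noise = noise,
                 seed = seed, config = config),
            class = "rw_importance")
}

#' @export
print.rw_importance <- function(x, ...) {
  cat(sprintf("<rw_importance> %d features x %d reps (subset %.2g, %s noise)\n",
              length(unique(x$reps$feature)), x$n_reps,
              x$subset_fraction, x$noise))
  print(utils::head(rank_importance(x), 10), row.names = FALSE)
  invisible(x)
}

#' Rank features by median importance
#'
#' @param dist an `rw_importance`
#' @return data.frame ordered by descending median `delta_r2` (ties broken
#'   alphabetically) with median, 2.5 and 97.5 percent quantiles
#' @export
rank_importance <- function(dist) {
  stopifnot(inherits(dist, "rw_importance"))
  sp <- split(dist$reps$delta_r2, dist$reps$feature)
  s <- data.frame(
    feature = names(sp),
    median = vapply(sp, stats::median, numeric(1)),
    q025 = vapply(sp, stats::quantile, numeric(1), probs = 0.025,
                  names = FALSE),
    q975 = vapply(sp, stats::quantile, numeric(1), probs = 0.975,
                  names = FALSE),
    row.names = NULL)
  s <- s[order(-s$median, s$feature), ]
  s$rank <- seq_len(nrow(s))
  rownames(s) <- NULL
  s
}

#' Partial dependence of the model on one or two features
#'
#' For each evaluation point, the chosen feature(s) are set to that value
#' in every data row and the predictions averaged — the model's mean
#' response as the feature sweeps its range while the remaining features
#' follow the data distribution. Evaluation points in the sparse tails of
#' the feature's marginal distribution are flagged as uncovered.
#'
#' @param model a `rich_ann`
#' @param data feature table (defaults to the fit table)
#' @param vars one or two feature names
#' @param resolution evaluation points per axis (default 20)
#' @param coverage_quantiles marginal quantile interval flagged as
#'   data-covered (default `c(0.05, 0.95)`): partial dependence is
#'   unreliable in the sparse tails of a feature's marginal, so grid
#'   points outside the inner 90 percent of the data are flagged
#' @return object of class `rw_pd`: data.frame with `x` (and `y` for two
#'   features), `yhat`, `covered`
#' @export
partial_dependence <- function(model, data = model$data, vars,
                               resolution = 20,
                               coverage_quantiles = c(0.05, 0.95)) {
  if (!all(vars %in% model$feature_names))
    stop("unknown feature(s): ",
         paste(setdiff(vars, model$feature_names), collapse = ", "))
  if (!length(vars) %in% 1:2) stop("`vars` must name 1 or 2 features")
  X <- .design_matrix(model$formula, data)$X
  cover <- function(v, pts) {
    q <- stats::quantile(v, coverage_quantiles, type = 7, names = FALSE)
    pts >= q[1] & pts <= q[2]
  }
  grids <- lapply(vars, function(v)
    seq(min(X[, v]), max(X[, v]), length.out = resolution))
  if (length(vars) == 1) {
    yhat <- vapply(grids[[1]], function(g) {
      Xp <- X; Xp[, vars] <- g
      mean(.mlp_forward(model$weights, Xp))
    }, numeric(1))
    out <- data.frame(x = grids[[1]], yhat = yhat,
                      covered = cover(X[, vars], grids[[1]]))
  } else {
    gg <- expand.grid(x = grids[[1]], y = grids[[2]])
    yhat <- vapply(seq_len(nrow(gg)), function(i) {
      Xp <- X
      Xp[, vars[1]] <- gg$x[i]
      Xp[, vars[2]] <- gg$y[i]
      mean(.mlp_forward(model$weights, Xp))
    }, numeric(1))
    out <- data.frame(gg, yhat = yhat,
                      covered = cover(X[, vars[1]], gg$x) &
                        cover(X[, vars[2]], gg$y))
  }
  structure(out, vars = vars, class = c("rw_pd", "data.frame"))
}

#' @export
plot.rw_pd <- function(x, ...) {
  vars <- attr(x, "vars")
  if (length(vars) == 1) {
    graphics::plot(x$x, x$yhat, type = "l", xlab = vars,
                   ylab = "partial dependence", ...)
    graphics::rug(x$x[x$covered])
  } else {
    z <- matrix(x$yhat, nrow = length(unique(x$x)))
    graphics::filled.contour(unique(x$x), unique(x$y), z,
                             xlab = vars[1], ylab = vars[2], ...)
  }
  invisible(x)
}

#' Resampled loess curve ensemble for one driver
#'
#' Repeatedly subsamples the table, fits a local regression of the
#' response on the feature through each subsample, and evaluates it on a
#' fixed grid; the pointwise median and 2.5/97.5 percent quantiles across
#' replicates summarise the bivariate relationship.
#'
#' @param data feature table
#' @param feature feature name
#' @param n_sub subsample size (default 10000; clamped to the table size
#'   with a warning)
#' @param n_reps replicates (default 100)
#' @param span,degree loess parameters (defaults 0.75, 2)
#' @param grid_n evaluation grid size (default 50)
#' @param seed integer seed
#' @param response response column (default `"response"`)
#' @return object of class `rw_curve_ensemble`: data.frame `x`, `median`,
#'   `lower`, `upper`
#' @export
pairwise_loess_ensemble <- function(data, feature, n_sub = 10000,
                                    n_reps = 100, span = 0.75, degree = 2,
                                    grid_n = 50, seed = 1L,
                                    response = "response") {
  x <- data[[feature]]
  y <- data[[response]]
  if (is.null(x)) stop("no feature column '", feature, "'")
  if (length(unique(x)) < 2) stop("feature '", feature, "' is constant")
  n <- length(x)
  if (n_sub > n) {
    warning("subsample size clamped to table size (", n, ")")
    n_sub <- n
  }
  grid <- seq(min(x), max(x), length.out = grid_n)
  set.seed(seed)
  curves <- matrix(NA_real_, n_reps, grid_n)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n, n_sub)
    d <- data.frame(x = x[idx], y = y[idx])
    fit <- stats::loess(y ~ x, data = d, span = span, degree = degree,
                        control = stats::loess.control(surface = "direct"))
    curves[r, ] <- stats::predict(fit, data.frame(x = grid))
  }
  qs <- apply(curves, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE)
  structure(data.frame(x = grid, median = qs[2, ], lower = qs[1, ],
                       upper = qs[3, ]),
            feature = feature, n_sub = n_sub, n_reps = n_reps,
            span = span, class = c("rw_curve_ensemble", "data.frame"))
}

#' @export
plot.rw_curve_ensemble <- function(x, ...) {
  graphics::plot(x$x, x$median, type = "l", ylim = range(x$lower, x$upper),
                 xlab = attr(x, "feature"), ylab = "response", ...)
  graphics::lines(x$x, x$lower, lty = 3)
  graphics::lines(x$x, x$upper, lty = 3)
  invisible(x)
}

#' Residual map (observed minus predicted)
#'
#' Positive residuals mark underpredicted (unexpectedly species-rich)
#' cells, negative residuals overpredicted ones. Defined exactly on cells
#' where both layers have values.
#'
#' @param observed,predicted `rw_layer`s on the same grid
#' @return an `rw_layer` (classes `rw_residual_map`, `rw_layer`) with a
#'   `summary` attribute
#' @export
residual_map <- function(observed, predicted) {
  stopifnot(inherits(observed, "rw_layer"), inherits(predicted, "rw_layer"))
  if (observed$grid$n_rows != predicted$grid$n_rows ||
      observed$grid$n_cols != predicted$grid$n_cols ||
      observed$grid$cell_km != predicted$grid$cell_km)
    stop("observed and predicted layers are on different grids")
  v <- observed$values - predicted$values
  out <- rw_layer(v, observed$grid, "residual")
  class(out) <- c("rw_residual_map", class(out))
  fin <- v[is.finite(v)]
  attr(out, "summary") <- c(mean = mean(fin), sd = stats::sd(fin),
                            min = min(fin), max = max(fin))
  out
}

#' Zonal (latitude-binned) mean profile
#'
#' Half-open latitude bins `[b, b + bin_deg)` covering [-90, 90); per-bin
#' mean over non-missing cells, empty bins flagged.
#'
#' @param layer an `rw_layer`
#' @param bin_deg bin width in degrees (default 2)
#' @return data.frame `bin_low`, `bin_high`, `mean`, `n_cells`, `empty`
#' @export
zonal_profile <- function(layer, bin_deg = 2) {
  stopifnot(inherits(layer, "rw_layer"))
  lat <- layer$grid$lat
  v <- layer$values
  ok <- is.finite(v)
  edges <- seq(-90, 90, by = bin_deg)
  if (edges[length(edges)] < 90) edges <- c(edges, 90)
  bin <- findInterval(lat, edges, rightmost.closed = TRUE)
  out <- data.frame(bin_low = edges[-length(edges)],
                    bin_high = edges[-1])
  out$n_cells <- vapply(seq_len(nrow(out)), function(b)
    sum(ok & bin == b), integer(1))
  out$mean <- vapply(seq_len(nrow(out)), function(b) {
    rows <- ok & bin == b
    if (any(rows)) mean(v[rows]) else NA_real_
  }, numeric(1))
  out$empty <- out$n_cells == 0
  out
}

#' Empirical semivariogram of a gridded field
#'
#' gamma(h) = mean of 0.5 (z_i - z_j)^2 over cell pairs whose
#' centroid distance (on the equal-area plane, km) falls in lag bin h.
#' All pairs are used when the cell count is below `exhaustive_below`;
#' otherwise `max_pairs` random pairs are drawn.
#'
#' @param layer an `rw_layer` (e.g. a residual map)
#' @param lag_edges lag bin edges in km; default 15 bins up to half the
#'   maximum span
#' @param max_pairs pair subsample size for large grids (default 1e6)
#' @param exhaustive_below use all pairs when fewer cells than this
#'   (default 1e4... cells, i.e. grids up to ~100 x 100)
#' @param seed seed for pair subsampling
#' @return data.frame of class `rw_semivariogram`: `lag_low`, `lag_high`,
#'   `lag_mid`, `gamma`, `n_pairs`
#' @export
empirical_semivariogram <- function(layer, lag_edges = NULL,
                                    max_pairs = 1e6,
                                    exhaustive_below = 1e4, seed = 1L) {
  stopifnot(inherits(layer, "rw_layer"))
  ok <- which(is.finite(layer$values))
  if (length(ok) < 2) stop("need at least 2 non-missing cells")
  x <- layer$grid$x[ok]
  y <- layer$grid$y[ok]
  z <- layer$values[ok]
  n <- length(ok)
  if (n < exhaustive_below) {
    dd <- as.numeric(stats::dist(cbind(x, y)))
    g2 <- as.numeric(stats::dist(z))^2 / 2
  } else {
    set.seed(seed)
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n, max_pairs, replace = TRUE)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    dd <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    g2 <- (z[i] - z[j])^2 / 2
  }
  if (is.null(lag_edges))
    lag_edges <- seq(0, max(dd) / 2, length.out = 16)
  bin <- findInterval(dd, lag_edges, rightmost.closed = TRUE)
  nb <- length(lag_edges) - 1
  out <- data.frame(lag_low = lag_edges[-length(lag_edges)],
                    lag_high = lag_edges[-1])
  out$lag_mid <- (out$lag_low + out$lag_high) / 2
  out$n_pairs <- vapply(seq_len(nb), function(b)
    sum(bin == b), integer(1))
  out$gamma <- vapply(seq_len(nb), function(b) {
    rows <- bin == b
    if (any(rows)) mean(g2[rows]) else NA_real_
  }, numeric(1))
  class(out) <- c("rw_semivariogram", "data.frame")
  out
}

#' @export
plot.rw_semivariogram <- function(x, ...) {
  graphics::plot(x$lag_mid, x$gamma, type = "b", xlab = "lag (km)",
                 ylab = expression(gamma(h)), ...)
  invisible(x)
}
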