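#' Equal-area analysis grids and gridded layers
#'
#' The analysis lives on a cylindrical equal-area grid (Lambert cylindrical,
#' standard parallel at the equator): x = R * lon, y = R * sin(lat), with R
#' the Earth radius in km. Square cells of side `cell_km` tile the projected
#' plane, so every cell has the same area regardless of latitude. Cells are
#' stored in row-major order, row 1 at the southern edge.
#'
#' @name grid
NULL

.EARTH_RADIUS_KM <- 6371

#' Build a cylindrical equal-area grid
#'
#' @param extent numeric length-4 vector `c(lon_min, lon_max, lat_min,
#'   lat_max)` in degrees. Defaults to the full globe.
#' @param cell_km cell side length in km (default 50).
#' @param mask initial domain flag for every cell: `"ocean"`, `"land"` or
#'   `"excluded"`. Domains are usually reassigned later from an elevation
#'   field via [assign_domains()].
#' @return an object of class `rw_grid`: a list with `n_rows`, `n_cols`,
#'   `cell_km`, projected centroid coordinates `x`, `y` (km), geographic
#'   centroids `lon`, `lat` (degrees, per cell, row-major), and `mask`.
#' @examples
#' g <- make_grid(c(-10, 10, -10, 10), cell_km = 100)
#' n_cells(g)
#' @export
make_grid <- function(extent = c(-180, 180, -90, 90), cell_km = 50,
                      mask = "ocean") {
  if (length(extent) != 4 || !is.numeric(extent) || anyNA(extent))
    stop("`extent` must be numeric c(lon_min, lon_max, lat_min, lat_max)")
  if (extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("degenerate extent: need lon_min < lon_max and lat_min < lat_max")
  if (!is.numeric(cell_km) || length(cell_km) != 1 || cell_km <= 0)
    stop("`cell_km` must be a single positive number")
  mask <- match.arg(mask, c("ocean", "land", "excluded"))

  R <- .EARTH_RADIUS_KM
  x_min <- R * extent[1] * pi / 180
  x_max <- R * extent[2] * pi / 180
  y_min <- R * sin(extent[3] * pi / 180)
  y_max <- R * sin(extent[4] * pi / 180)

  n_cols <- max(1L, as.integer(ceiling((x_max - x_min) / cell_km - 1e-9)))
  n_rows <- max(1L, as.integer(ceiling((y_max - y_min) / cell_km - 1e-9)))

  x <- x_min + (seq_len(n_cols) - 0.5) * cell_km
  y <- y_min + (seq_len(n_rows) - 0.5) * cell_km

  lon <- x / R * 180 / pi
  # ceiling can overshoot the pole by a fraction of a cell; clamp the sine
  lat <- asin(pmin(1, pmax(-1, y / R))) * 180 / pi

  g <- structure(list(
    n_rows = n_rows, n_cols = n_cols, cell_km = cell_km,
    extent = extent,
    x = rep(x, times = n_rows),
    y = rep(y, each = n_cols),
    lon = rep(lon, times = n_rows),
    lat = rep(lat, each = n_cols),
    mask = rep(mask, n_rows * n_cols)
  ), class = "rw_grid")
  g
}

#' Number of cells in a grid
#' @param grid an `rw_grid`
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "rw_grid"))
  grid$n_rows * grid$n_cols
}

#' Cell centroid table
#'
#' @param grid an `rw_grid`
#' @return data.frame with `cell_id`, `row`, `col`, `x`, `y` (km),
#'   `lon`, `lat` (degrees) and `mask`.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "rw_grid"))
  n <- n_cells(grid)
  data.frame(
    cell_id = seq_len(n),
    row = rep(seq_len(grid$n_rows), each = grid$n_cols),
    col = rep(seq_len(grid$n_cols), times = grid$n_rows),
    x = grid$x, y = grid$y, lon = grid$lon, lat = grid$lat,
    mask = grid$mask
  )
}

#' @export
print.rw_grid <- function(x, ...) {
  cat(sprintf("<rw_grid> %d x %d cells of %g km (%d cells)\n",
              x$n_rows, x$n_cols, x$cell_km, n_cells(x)))
  cat(sprintf("  lon [%.2f, %.2f], lat [%.2f, %.2f]\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  cat("  mask:", paste(sprintf("%s=%d", names(table(x$mask)), table(x$mask)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Gridded layer (one value per cell)
#'
#' @param values numeric vector, one value per grid cell (row-major).
#' @param grid the `rw_grid` the values live on.
#' @param name optional layer name.
#' @export
rw_layer <- function(values, grid, name = "") {
  stopifnot(inherits(grid, "rw_grid"))
  if (length(values) != n_cells(grid))
    stop("`values` length (", length(values), ") != number of grid cells (",
         n_cells(grid), ")")
  structure(list(values = as.numeric(values), grid = grid, name = name),
            class = "rw_layer")
}

#' @export
print.rw_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<rw_layer> '%s' on %dx%d grid; %d finite cells",
              x$name, x$grid$n_rows, x$grid$n_cols, length(v)))
  if (length(v))
    cat(sprintf("; range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Gridded monthly time series (cells x months)
#'
#' @param values numeric matrix, `n_cells(grid)` rows, one column per month.
#' @param grid the `rw_grid`.
#' @param name optional series name.
#' @export
rw_series <- function(values, grid, name = "") {
  stopifnot(inherits(grid, "rw_grid"))
  values <- as.matrix(values)
  if (nrow(values) != n_cells(grid))
    stop("series must have one row per grid cell")
  structure(list(values = values, grid = grid, name = name),
            class = "rw_series")
}

#' @export
print.rw_series <- function(x, ...) {
  cat(sprintf("<rw_series> '%s': %d cells x %d months\n",
              x$name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Assign land/ocean domains by thresholding a field
#'
#' Splits the world into a land and an ocean domain so the two realms can be
#' modelled separately. Cells whose field value exceeds the
#' `1 - land_fraction` quantile become `"land"`, the rest `"ocean"`;
#' previously excluded cells stay excluded.
#'
#' @param grid an `rw_grid`
#' @param layer an `rw_layer` (typically elevation)
#' @param land_fraction fraction of (non-excluded) cells to mark as land.
#' @return a new `rw_grid` with the updated mask.
#' @export
assign_domains <- function(grid, layer, land_fraction = 0.3) {
  stopifnot(inherits(grid, "rw_grid"), inherits(layer, "rw_layer"))
  if (land_fraction < 0 || land_fraction > 1)
    stop("`land_fraction` must be in [0, 1]")
  keep <- grid$mask != "excluded"
  thr <- stats::quantile(layer$values[keep], 1 - land_fraction,
                         type = 7, names = FALSE)
  mask <- ifelse(layer$values > thr, "land", "ocean")
  mask[!keep] <- "excluded"
  grid$mask <- mask
  grid
}

#' Cells belonging to a domain
#' @param grid an `rw_grid`
#' @param domain `"land"`, `"ocean"` or `"all"` (all non-excluded cells)
#' @return integer cell ids
#' @export
domain_cells <- function(grid, domain = c("all", "land", "ocean")) {
  domain <- match.arg(domain)
  if (domain == "all") which(grid$mask != "excluded")
  else which(grid$mask == domain)
}

# row/col <-> cell id helpers (row-major, row 1 southernmost)
.cell_id <- function(grid, row, col) (row - 1L) * grid$n_cols + col
.cell_row <- function(grid, id) (id - 1L) %/% grid$n_cols + 1L
.cell_col <- function(grid, id) (id - 1L) %% grid$n_cols + 1L

#' View a layer as a row x col matrix
#' @param layer an `rw_layer`
#' @export
layer_matrix <- function(layer) {
  stopifnot(inherits(layer, "rw_layer"))
  matrix(layer$values, nrow = layer$grid$n_rows,
         ncol = layer$grid$n_cols, byrow = TRUE)
}
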