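#' Plain-text input and output
#'
#' Gridded layers and series travel as long-format CSV (portable and
#' diff-able), occurrence records and feature tables as CSV with a JSON
#' provenance sidecar, configs as YAML, and fitted models as JSON
#' (architecture + weights), so a run can be reproduced from its artifacts
#' alone.
#'
#' @name io
NULL

#' Write a layer as long-format CSV
#' @param layer an `rw_layer`
#' @param path output file
#' @export
write_layer_csv <- function(layer, path) {
  stopifnot(inherits(layer, "rw_layer"))
  g <- grid_coords(layer$grid)
  df <- data.frame(cell_id = g$cell_id, row = g$row, col = g$col,
                   lon = g$lon, lat = g$lat, value = layer$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a layer written by [write_layer_csv()]
#' @param path CSV file
#' @param grid the grid the layer lives on
#' @export
read_layer_csv <- function(path, grid) {
  df <- utils::read.csv(path)
  v <- rep(NA_real_, n_cells(grid))
  v[df$cell_id] <- df$value
  rw_layer(v, grid, tools::file_path_sans_ext(basename(path)))
}

#' Write a monthly series as long-format CSV
#' @param series an `rw_series`
#' @param path output file
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "rw_series"))
  T_len <- ncol(series$values)
  df <- data.frame(cell_id = rep(seq_len(nrow(series$values)), T_len),
                   month = rep(seq_len(T_len), each = nrow(series$values)),
                   value = as.numeric(series$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read occurrence records
#' @param occurrences an `rw_occurrences` data.frame
#' @param path CSV file
#' @export
write_occurrences_csv <- function(occurrences, path) {
  utils::write.csv(as.data.frame(occurrences), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @export
read_occurrences_csv <- function(path) {
  occ <- utils::read.csv(path)
  need <- c("species_id", "lon", "lat", "thermal_value")
  miss <- setdiff(need, names(occ))
  if (length(miss))
    stop("occurrence CSV is missing columns: ", paste(miss, collapse = ", "))
  class(occ) <- c("rw_occurrences", "data.frame")
  occ
}

#' Write a feature table with its provenance sidecar
#'
#' The table goes to `path` as CSV; the transform provenance (per-feature
#' truncation quantiles and scaling, response scaling) to `paste0(path,
#' ".provenance.json")`.
#'
#' @param table an `rw_features`
#' @param path CSV file
#' @export
write_feature_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(attr(table, "provenance"),
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialise a fitted network to JSON
#'
#' Stores architecture, weights, feature names and transform provenance;
#' [model_from_json()] restores an object whose predictions equal the
#' original's.
#'
#' @param model a `rich_ann`
#' @param path JSON file
#' @export
model_to_json <- function(model, path) {
  stopifnot(inherits(model, "rich_ann"))
  obj <- list(
    type = "rich_ann",
    config = unclass(model$config),
    feature_names = model$feature_names,
    intercept_only = model$intercept_only,
    weights = lapply(model$weights, function(w)
      list(dim = dim(w$W), W = as.numeric(w$W), b = as.numeric(w$b))),
    provenance = model$provenance,
    metrics = model$metrics
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  weights <- lapply(obj$weights, function(w) {
    d <- as.integer(unlist(w$dim))
    list(W = matrix(as.numeric(unlist(w$W)), d[1], d[2]),
         b = as.numeric(unlist(w$b)))
  })
  cfg_fields <- obj$config[names(obj$config) %in%
                             names(formals(ann_config))]
  structure(list(
    weights = weights,
    config = do.call(ann_config, lapply(cfg_fields, unlist)),
    feature_names = as.character(unlist(obj$feature_names)),
    intercept_only = isTRUE(unlist(obj$intercept_only)),
    provenance = obj$provenance,
    metrics = obj$metrics,
    formula = stats::as.formula("response ~ .")
  ), class = "rich_ann")
}

#' Write a world config (or any config list) as YAML
#' @param config a config object/list (functions are dropped)
#' @param path YAML file
#' @export
write_config_yaml <- function(config, path) {
  strip <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) {
      out <- lapply(x, strip)
      out[!vapply(out, is.null, TRUE)]
    } else x
  }
  yaml::write_yaml(strip(unclass(config)), path)
  invisible(path)
}
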