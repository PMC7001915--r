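#' End-to-end seeded pipeline
#'
#' One configuration drives the whole analysis — generate a world, screen
#' marine occurrence records, engineer features, fit one network per
#' domain, and interrogate each fit — writing every artifact plus a
#' manifest of seeds, parameters and file checksums. Stage seeds are
#' derived deterministically from the global seed and the stage name, so
#' adding stages never perturbs earlier randomness and two runs with one
#' seed are byte-identical.
#'
#' @name pipeline
NULL

# deterministic stage seed below 2^31
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(global_seed)) * 10007 + h * 97) %% 2147483629)
}

#' Pipeline configuration
#'
#' @param world an [world_config()] (its seed is overridden by the derived
#'   world-stage seed)
#' @param extent,cell_km grid geometry
#' @param domains domains to model (`"land"`, `"ocean"` or both). Screening
#'   applies to the ocean domain only: marine richness comes from point
#'   records of screened species, terrestrial richness from stacked ranges.
#' @param screening list: `enabled`, `threshold`, `min_sufficient`
#'   (compute per-species minimum sufficient counts), `reps`, `coverage`
#' @param model list: `config` ([ann_config()]), optional `candidates`
#'   (list of configs for [cross_validate()]) and `k`
#' @param interpretation list: `importance_reps`, `subset_fraction`,
#'   `pd_vars` (NULL = top 2 ranked features), `loess_n_sub`,
#'   `loess_reps`, `span`, `variogram_max_pairs`
#' @param output_dir directory for artifacts
#' @param global_seed integer; all stage seeds derive from it
#' @return object of class `rw_pipeline_config`
#' @export
pipeline_config <- function(world = world_config(),
                            extent = c(-180, 180, -60, 60),
                            cell_km = 50,
                            domains = c("ocean", "land"),
                            screening = list(),
                            model = list(),
                            interpretation = list(),
                            output_dir = tempfile("richworld_run_"),
                            global_seed = 1L) {
  screening <- utils::modifyList(list(
    enabled = TRUE, threshold = 41, min_sufficient = FALSE,
    reps = 200, coverage = 0.95), screening)
  model <- utils::modifyList(list(
    config = ann_config(), candidates = NULL, k = 5), model)
  interpretation <- utils::modifyList(list(
    importance_reps = 30, subset_fraction = 0.8, pd_vars = NULL,
    loess_n_sub = 2000, loess_reps = 30, span = 0.75,
    variogram_max_pairs = 2e5), interpretation)
  structure(list(world = world, extent = extent, cell_km = cell_km,
                 domains = match.arg(domains, c("ocean", "land"),
                                     several.ok = TRUE),
                 screening = screening, model = model,
                 interpretation = interpretation,
                 output_dir = output_dir,
                 global_seed = as.integer(global_seed)),
            class = "rw_pipeline_config")
}

#' Demo pipeline configuration
#'
#' A complete run at demonstration scale: 100 x 100 cell grid, 200
#' species, 30 driver features, reduced interpretation replicate counts.
#'
#' @param output_dir artifact directory
#' @param global_seed integer seed
#' @export
demo_pipeline_config <- function(output_dir = tempfile("richworld_demo_"),
                                 global_seed = 1L) {
  pipeline_config(
    world = world_config(n_species = 200, n_true_drivers = 3,
                         n_distractor_drivers = 27, n_years = 10),
    extent = c(-40, 5, -22, 22), cell_km = 50,  # ~100 x 100 cells
    # a ~10k-cell table sees far fewer gradient updates per epoch than a
    # full-size dataset; scale epochs up so the demo fit is converged
    model = list(config = ann_config(epochs = 150)),
    interpretation = list(importance_reps = 10, loess_n_sub = 1500,
                          loess_reps = 20),
    output_dir = output_dir, global_seed = global_seed)
}

.run_stage <- function(manifest, name, fun) {
  res <- fun()
  manifest$stages[[name]] <- list(seed = res$seed, files = res$files)
  manifest$objects[[name]] <- res$objects
  manifest
}

#' Run the full pipeline
#'
#' Executes generate -> screen (ocean) -> featurize -> fit -> interpret per
#' domain, writes artifacts under `config$output_dir` and a
#' `manifest.json` recording the configuration digest, stage seeds,
#' metrics and md5 checksums of every written file. Stage outputs can be
#' recomputed individually via `stages`.
#'
#' @param config an [pipeline_config()]
#' @param stages subset of `c("world", "screening", "features", "model",
#'   "interpretation")` to run (default all, in order)
#' @param quiet suppress progress messages
#' @return the manifest (invisibly also written to
#'   `output_dir/manifest.json`)
#' @export
run_pipeline <- function(config,
                         stages = c("world", "screening", "features",
                                    "model", "interpretation"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "rw_pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  out <- function(...) file.path(config$output_dir, ...)
  files <- character()
  add_file <- function(path) files <<- c(files, path)

  manifest <- list(
    package = "richworld",
    version = as.character(utils::packageVersion("richworld")),
    global_seed = config$global_seed,
    domains = config$domains,
    stage_seeds = list(),
    metrics = list(),
    screening = list()
  )

  # ---- world ----
  ws <- stage_seed(config$global_seed, "world")
  manifest$stage_seeds$world <- ws
  wc <- config$world
  wc$seed <- ws
  say("stage world (seed ", ws, ")")
  world <- simulate_world(wc, extent = config$extent,
                          cell_km = config$cell_km, richness = "ranges")
  grid <- world$grid
  if ("world" %in% stages) {
    write_layer_csv(world$drivers$static$elevation, out("elevation.csv"))
    add_file("elevation.csv")
    write_occurrences_csv(world$occurrences, out("occurrences.csv"))
    add_file("occurrences.csv")
    write_config_yaml(wc, out("world_config.yaml"))
    add_file("world_config.yaml")
  }

  # ---- screening (marine point records only) ----
  retained_species <- NULL
  if (config$screening$enabled && "ocean" %in% config$domains) {
    ss <- stage_seed(config$global_seed, "screening")
    manifest$stage_seeds$screening <- ss
    say("stage screening (seed ", ss, ")")
    ocean_sp <- which(world$ranges$niches$domain == "ocean")
    occ <- world$occurrences[world$occurrences$species_id %in% ocean_sp, ]
    scr <- screen_species(occ, threshold = config$screening$threshold,
                          compute_min_sufficient =
                            config$screening$min_sufficient,
                          reps = config$screening$reps,
                          coverage = config$screening$coverage, seed = ss)
    retained_species <- as.integer(
      scr$report$species_id[scr$report$passed])
    manifest$screening <- list(
      threshold = config$screening$threshold,
      n_species_in = nrow(scr$report),
      n_species_retained = length(retained_species),
      n_records_retained = nrow(scr$records))
    if ("screening" %in% stages) {
      utils::write.csv(scr$report, out("screening_report.csv"),
                       row.names = FALSE)
      add_file("screening_report.csv")
      rar <- latitudinal_rarefaction(scr$records)
      rar_df <- do.call(rbind, lapply(rar$bins, function(b) {
        if (b$empty) return(NULL)
        data.frame(bin_low = b$bin_low, bin_high = b$bin_high, b$curve)
      }))
      utils::write.csv(rar_df, out("rarefaction.csv"), row.names = FALSE)
      add_file("rarefaction.csv")
    }
  } else manifest$screening <- list(enabled = FALSE)

  # ---- per-domain: features, model, interpretation ----
  for (dom in config$domains) {
    say("domain ", dom)
    dom_dir <- out(dom)
    dir.create(dom_dir, showWarnings = FALSE)
    sp_dom <- which(world$ranges$niches$domain == dom)
    if (dom == "ocean" && !is.null(retained_species))
      sp_dom <- intersect(sp_dom, retained_species)
    richness <- stack_ranges_to_richness(world$ranges, grid,
                                         species = sp_dom)

    fs <- stage_seed(config$global_seed, paste0("features_", dom))
    manifest$stage_seeds[[paste0("features_", dom)]] <- fs
    layers <- standard_feature_layers(world$drivers)
    tab <- build_feature_table(layers, richness, grid, domain = dom)
    if ("features" %in% stages) {
      write_feature_table_csv(tab, file.path(dom_dir, "features.csv"))
      add_file(file.path(dom, "features.csv"))
      add_file(file.path(dom, "features.csv.provenance.json"))
    }

    msd <- stage_seed(config$global_seed, paste0("model_", dom))
    manifest$stage_seeds[[paste0("model_", dom)]] <- msd
    say("  fitting (seed ", msd, ", n = ", nrow(tab), ")")
    cfg <- config$model$config
    cfg$seed <- msd
    if (!is.null(config$model$candidates)) {
      cands <- lapply(config$model$candidates, function(cc) {
        cc$seed <- msd; cc })
      cv <- cross_validate(tab, cands, k = config$model$k, seed = msd)
      cfg <- cv$selected
      manifest$metrics[[paste0(dom, "_cv")]] <- list(
        selected = cv$selected_index,
        mean_rmse = cv$summary$mean_rmse,
        var_rmse = cv$summary$var_rmse)
    }
    split <- split_train_test(nrow(tab), 0.8, msd)
    fit <- rich_ann(response ~ ., tab, config = cfg, split = split)
    manifest$metrics[[dom]] <- list(
      n_cells = nrow(tab),
      train_r2 = fit$metrics$train$r2, train_rmse = fit$metrics$train$rmse,
      test_r2 = fit$metrics$test$r2, test_rmse = fit$metrics$test$rmse)
    if ("model" %in% stages) {
      model_to_json(fit, file.path(dom_dir, "model.json"))
      add_file(file.path(dom, "model.json"))
    }
    pred <- predict_surface(fit, tab, grid)
    obs <- rw_layer(ifelse(seq_len(n_cells(grid)) %in% tab$cell_id,
                           tab$response[match(seq_len(n_cells(grid)),
                                              tab$cell_id)], NA_real_),
                    grid, "observed_response")
    res <- residual_map(obs, pred)
    if ("model" %in% stages) {
      write_layer_csv(pred, file.path(dom_dir, "predicted.csv"))
      add_file(file.path(dom, "predicted.csv"))
      write_layer_csv(res, file.path(dom_dir, "residuals.csv"))
      add_file(file.path(dom, "residuals.csv"))
    }

    if ("interpretation" %in% stages) {
      is_seed <- stage_seed(config$global_seed,
                            paste0("interpretation_", dom))
      manifest$stage_seeds[[paste0("interpretation_", dom)]] <- is_seed
      ip <- config$interpretation
      say("  interpretation (seed ", is_seed, ")")
      imp <- permutation_importance(tab, config = cfg,
                                    n_reps = ip$importance_reps,
                                    subset_fraction = ip$subset_fraction,
                                    seed = is_seed)
      utils::write.csv(imp$reps, file.path(dom_dir, "importance_reps.csv"),
                       row.names = FALSE)
      add_file(file.path(dom, "importance_reps.csv"))
      rk <- rank_importance(imp)
      jsonlite::write_json(rk, file.path(dom_dir, "importance_rank.json"),
                           auto_unbox = TRUE, digits = NA)
      add_file(file.path(dom, "importance_rank.json"))

      pd_vars <- ip$pd_vars
      if (is.null(pd_vars)) pd_vars <- utils::head(rk$feature, 2)
      pd <- partial_dependence(fit, tab, pd_vars[1])
      utils::write.csv(as.data.frame(pd),
                       file.path(dom_dir, "pd_curve.csv"),
                       row.names = FALSE)
      add_file(file.path(dom, "pd_curve.csv"))
      if (length(pd_vars) >= 2) {
        pd2 <- partial_dependence(fit, tab, pd_vars[1:2])
        utils::write.csv(as.data.frame(pd2),
                         file.path(dom_dir, "pd_surface.csv"),
                         row.names = FALSE)
        add_file(file.path(dom, "pd_surface.csv"))
      }
      le <- pairwise_loess_ensemble(tab, pd_vars[1],
                                    n_sub = min(ip$loess_n_sub, nrow(tab)),
                                    n_reps = ip$loess_reps,
                                    span = ip$span, seed = is_seed)
      utils::write.csv(as.data.frame(le),
                       file.path(dom_dir, "loess_ensemble.csv"),
                       row.names = FALSE)
      add_file(file.path(dom, "loess_ensemble.csv"))
      zp <- zonal_profile(obs)
      utils::write.csv(zp, file.path(dom_dir, "zonal_profile.csv"),
                       row.names = FALSE)
      add_file(file.path(dom, "zonal_profile.csv"))
      sv <- empirical_semivariogram(res, max_pairs =
                                      ip$variogram_max_pairs,
                                    seed = is_seed)
      utils::write.csv(as.data.frame(sv),
                       file.path(dom_dir, "semivariogram.csv"),
                       row.names = FALSE)
      add_file(file.path(dom, "semivariogram.csv"))
    }
  }

  files <- sort(unique(files))
  sums <- tools::md5sum(file.path(config$output_dir, files))
  manifest$files <- stats::setNames(as.list(unname(sums)), files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
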