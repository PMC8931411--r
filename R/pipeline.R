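#' Pipeline configuration
#'
#' Describes one sample-transfer experiment: which years are historical,
#' which is the target, which historical-year subsets ("schemes") to pool
#' generated samples from, and the stage parameters. Scenes either come from
#' the built-in simulator (`scene` is a [scene_config()]) or from directories
#' on disk (`scene_dirs`, named by year, read with [read_scene()], plus
#' `sample_paths` named by year).
#'
#' A single global `seed` derives per-stage seeds by fixed offsets
#' (simulation +0, surveys +1000, screening +2000, validation split +3000,
#' forest +4000), all recorded in the run manifest.
#'
#' @param scene a [scene_config()] (simulated mode) or `NULL`.
#' @param scene_dirs named list year -> directory (on-disk mode).
#' @param sample_paths named list year -> samples CSV/GeoJSON (on-disk mode).
#' @param historical_years,target_year year labels; the target year must not
#'   be historical.
#' @param schemes named list of historical-year subsets to pool; default one
#'   scheme per single historical year plus `"all"`.
#' @param n_per_class simulated field-survey size per class and year.
#' @param window,n_points,k_range,doy_grid,forest stage parameters (see the
#'   stage functions).
#' @param classify_map also classify the full target scene (slower).
#' @param baseline also run the train-on-true-target-samples ablation.
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scene = NULL, scene_dirs = NULL,
                            sample_paths = NULL,
                            historical_years, target_year, schemes = NULL,
                            n_per_class = 30L, window = 5L, n_points = 100L,
                            k_range = c(2L, 20L),
                            doy_grid = seq(140, 290, by = 10),
                            forest = list(n_trees = 150L),
                            classify_map = FALSE, baseline = TRUE,
                            seed = 1L) {
  historical_years <- as.character(historical_years)
  target_year <- as.character(target_year)
  if (target_year %in% historical_years)
    stop("target_year must not be among historical_years")
  if (is.null(schemes)) {
    schemes <- as.list(setNames(historical_years, historical_years))
    if (length(historical_years) > 1) schemes$all <- historical_years
  }
  structure(list(scene = scene, scene_dirs = scene_dirs,
                 sample_paths = sample_paths,
                 historical_years = historical_years,
                 target_year = target_year, schemes = schemes,
                 n_per_class = as.integer(n_per_class),
                 window = as.integer(window), n_points = as.integer(n_points),
                 k_range = as.integer(k_range), doy_grid = doy_grid,
                 forest = forest, classify_map = isTRUE(classify_map),
                 baseline = isTRUE(baseline), seed = as.integer(seed)),
            class = "pipeline_config")
}

# polynomial rolling hash (mod 2^31 - 1, exact in doubles) over the
# serialized config; recorded in every artifact header
.config_hash <- function(config) {
  bytes <- charToRaw(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      force = TRUE, digits = NA))
  h <- 17
  for (b in as.integer(bytes)) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a sample-transfer experiment end to end
#'
#' simulate (or load) -> select per-feature curve models -> transfer each
#' historical sample to a potential target-year sample -> screen per crop ->
#' pool per scheme -> train the forest -> evaluate on the held-out 30% of the
#' target-year samples (optionally also classify the full scene). Every
#' artifact is written under `out_dir` with the stage seed and config hash in
#' the manifest; a rerun with the same config is bit-identical for the
#' deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return invisibly, the summary table also written to
#'   `out_dir/summary.csv`.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  seeds <- list(scene = config$seed, survey = config$seed + 1000L,
                screen = config$seed + 2000L, split = config$seed + 3000L,
                forest = config$seed + 4000L)

  years <- c(config$historical_years, config$target_year)
  if (!is.null(config$scene)) {
    sc <- config$scene
    sc$years <- years
    sc$seed <- seeds$scene
    sim <- generate_scene_series(sc)
    scenes <- sim$scenes
    samples <- setNames(lapply(seq_along(years), function(i)
      draw_field_samples(sim$truth, years[i], config$n_per_class,
                         seed = seeds$survey + i)), years)
    classes <- sc$crop_classes
  } else {
    scenes <- lapply(config$scene_dirs[years], read_scene)
    samples <- lapply(config$sample_paths[years], read_samples)
    classes <- sort(unique(unlist(lapply(samples, function(s) s$class))))
  }

  # one winning curve model per feature, from the first historical year's
  # pooled sample series
  y0 <- config$historical_years[1]
  sbf <- lapply(setNames(SIMILARITY_FEATURES, SIMILARITY_FEATURES),
                function(f) lapply(seq_len(nrow(samples[[y0]])), function(i)
                  pixel_feature_series(scenes[[y0]], samples[[y0]]$row[i],
                                       samples[[y0]]$col[i], f)))
  model_sel <- select_feature_models(sbf)
  jsonlite::write_json(list(models = as.list(model_sel$models),
                            summary = model_sel$summary, config_hash = hash),
                       file.path(out_dir, "feature_models.json"),
                       auto_unbox = TRUE, digits = NA)

  # per historical year: transfer + screen
  per_year <- list()
  for (y in config$historical_years) {
    pot <- select_potential_samples(samples[[y]], scenes[[y]],
                                    scenes[[config$target_year]],
                                    model_sel$models, config$window,
                                    config$n_points)
    scr <- screen_samples(pot$samples, pot$features, config$k_range[1],
                          config$k_range[2], seed = seeds$screen)
    ydir <- file.path(out_dir, paste0("year_", y))
    dir.create(ydir, showWarnings = FALSE)
    write_samples(pot$samples, file.path(ydir, "potential.csv"))
    data.table::fwrite(pot$skipped, file.path(ydir, "skipped.csv"))
    write_samples(scr$samples, file.path(ydir, "generated.csv"))
    jsonlite::write_json(c(scr$report, list(config_hash = hash)),
                         file.path(ydir, "screening.json"),
                         auto_unbox = TRUE, digits = NA)
    per_year[[y]] <- scr$samples
  }

  # target-year validation split
  sp <- split_validation(samples[[config$target_year]], 0.7,
                         seed = seeds$split)
  tstack <- scenes[[config$target_year]]
  fm_test <- build_feature_matrix(sp$test, tstack, model_sel$models,
                                  config$doy_grid)
  fcfg <- forest_config(n_trees = config$forest$n_trees %||% 150L,
                        mtry = config$forest$mtry,
                        seed = seeds$forest)

  eval_scheme <- function(train_samples, name) {
    fm_tr <- build_feature_matrix(train_samples, tstack, model_sel$models,
                                  config$doy_grid)
    cls <- train_forest(fm_tr, fcfg, classes = classes)
    pred <- predict(cls, fm_test)
    keep <- !is.na(pred)
    cm <- confusion_matrix(sp$test$class[keep], pred[keep], classes)
    rep <- accuracy_metrics(cm)
    sdir <- file.path(out_dir, paste0("scheme_", name))
    dir.create(sdir, showWarnings = FALSE)
    data.table::fwrite(data.table::as.data.table(cm$counts, keep.rownames =
                                                   "reference"),
                       file.path(sdir, "confusion.csv"))
    jsonlite::write_json(list(scheme = name, oa = rep$oa,
                              per_class = rep$per_class,
                              n_train = cls$n_train, n_test = sum(keep),
                              config_hash = hash),
                         file.path(sdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (config$classify_map) {
      map <- classify_scene(cls, tstack, model_sel$models, config$doy_grid)
      data.table::fwrite(data.table::as.data.table(map$labels),
                         file.path(sdir, "map.csv"), col.names = FALSE)
    }
    data.table::data.table(scheme = name, n_train = cls$n_train, oa = rep$oa,
                           mean_f1 = mean(rep$per_class$f1))
  }

  rows <- list()
  for (nm in names(config$schemes)) {
    pool <- data.table::rbindlist(per_year[config$schemes[[nm]]])
    if (!nrow(pool)) { warning("scheme ", nm, " has no generated samples")
      next }
    rows[[nm]] <- eval_scheme(pool, nm)
  }
  if (config$baseline)
    rows$baseline <- eval_scheme(sp$train, "baseline")

  summary <- data.table::rbindlist(rows)
  data.table::fwrite(summary, file.path(out_dir, "summary.csv"))
  jsonlite::write_json(list(config = unclass(config), config_hash = hash,
                            seeds = seeds,
                            artifacts = list.files(out_dir, recursive = TRUE)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(summary)
}

#' Summarize completed runs
#'
#' Reads the per-scheme `report.json` files of one or more run directories
#' into a comparison table, one row per scheme, sorted by overall accuracy;
#' the best-OA scheme is flagged and the baseline labeled distinctly.
#'
#' @param run_dirs character vector of run directories.
#' @return data.table `(run, scheme, kind, oa, mean_f1, best)`; schemes whose
#'   report is missing appear with `NA` metrics and `incomplete = TRUE`.
#' @export
summarize_runs <- function(run_dirs) {
  rows <- list()
  for (rd in run_dirs) {
    sdirs <- list.dirs(rd, recursive = FALSE)
    sdirs <- sdirs[grepl("^scheme_", basename(sdirs))]
    for (sd in sdirs) {
      nm <- sub("^scheme_", "", basename(sd))
      rp <- file.path(sd, "report.json")
      if (!file.exists(rp)) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          run = rd, scheme = nm, kind = "generated", oa = NA_real_,
          mean_f1 = NA_real_, incomplete = TRUE)
        next
      }
      r <- jsonlite::read_json(rp, simplifyVector = TRUE)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        run = rd, scheme = nm,
        kind = if (nm == "baseline") "baseline" else "generated",
        oa = r$oa, mean_f1 = mean(r$per_class$f1), incomplete = FALSE)
    }
  }
  if (!length(rows)) stop("no completed runs found")
  out <- data.table::rbindlist(rows)
  out <- out[order(-out$oa)]
  out$best <- !out$incomplete & out$oa == max(out$oa, na.rm = TRUE)
  out[]
}
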