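# Pipeline orchestration: YAML config, stage execution, run manifests.
#
# Each stage is runnable standalone on persisted intermediates, so a full
# study can be driven either from R or from the thin command-line wrapper
# shipped in inst/cli/habnet.R.

PIPELINE_STAGES <- c("simulate", "features", "sample", "train", "predict",
                     "calibrate", "ablate", "compare", "season", "burden")

config_schema <- function() {
  list(
    common = c("workdir", "seed"),
    simulate = c("n_lat", "n_lon", "years", "start_year", "effort"),
    features = c("climate"),
    sample = c("observations", "derived", "mask", "seq_len", "absence_ratio"),
    train = c("observations", "derived", "mask", "seq_len", "absence_ratio",
              "split", "max_epochs", "batch_size", "hidden_sizes",
              "learning_rate", "patience_final", "patience_cv"),
    predict = c("model", "derived", "dates"),
    calibrate = c("model", "raw_scores"),
    ablate = c("observations", "derived", "mask", "seq_lens", "splits",
               "leave_out", "max_epochs"),
    compare = c("map_a", "map_b", "thresholds"),
    season = c("fnr", "year", "mass"),
    burden = c("fnr_dirs", "population", "threshold", "years", "regions")
  )
}

#' Validate a pipeline configuration
#'
#' Checks that every key is known for the requested stage (schema
#' validation) and that referenced input files exist.
#'
#' @param config Named list (parsed YAML).
#' @param stage One of the pipeline stage names.
#' @return `config`, invisibly; errors list the offending keys.
#' @export
validate_config <- function(config, stage) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  schema <- config_schema()
  allowed <- c(schema$common, schema[[stage]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s) for stage '", stage, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  path_keys <- intersect(names(config),
                         c("climate", "observations", "derived", "mask",
                           "model", "raw_scores", "map_a", "map_b", "fnr",
                           "population"))
  for (k in path_keys)
    if (!file.exists(config[[k]]))
      stop("input '", k, "' does not exist: ", config[[k]], call. = FALSE)
  invisible(config)
}

stamp_checksums <- function(files) {
  files <- as.character(files)
  files <- files[file.exists(files)]
  # directory inputs (raster trees) are represented by their sidecar
  isdir <- dir.exists(files)
  files[isdir] <- file.path(files[isdir], "grid.json")
  files <- files[file.exists(files)]
  if (!length(files)) return(list())
  as.list(tools::md5sum(files))
}

#' Run one pipeline stage
#'
#' Executes the stage against the inputs named in `config`, writes its
#' outputs under `config$workdir`, and drops a JSON run manifest
#' (`manifest_<stage>.json`) recording the config snapshot, seed, input
#' and output checksums, timing, and package version. Reruns with
#' identical inputs and seed reproduce identical outputs.
#'
#' @param config Named list, or path to a YAML file.
#' @param stage Stage name; one of `simulate`, `features`, `sample`,
#'   `train`, `predict`, `calibrate`, `ablate`, `compare`, `season`,
#'   `burden`.
#' @param log Function called with progress messages (default
#'   `message`); pass `function(...) {}` to silence.
#' @return Stage-specific result, invisibly; side effect: files +
#'   manifest under `workdir`.
#' @export
run_pipeline <- function(config, stage, log = message) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stage <- match.arg(stage, PIPELINE_STAGES)
  validate_config(config, stage)
  wd <- config$workdir %||% "."
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  t0 <- Sys.time()
  in_files <- unlist(config[intersect(names(config),
                                      c("climate", "observations", "derived",
                                        "mask", "model", "raw_scores",
                                        "map_a", "map_b", "fnr",
                                        "population"))])
  log(sprintf("[habnet] stage %s starting (seed %d)", stage, seed))
  result <- switch(stage,
    simulate = stage_simulate(config, wd, seed),
    features = stage_features(config, wd),
    sample = stage_sample(config, wd, seed),
    train = stage_train(config, wd, seed),
    predict = stage_predict(config, wd),
    calibrate = stage_calibrate(config, wd),
    ablate = stage_ablate(config, wd, seed),
    compare = stage_compare(config, wd),
    season = stage_season(config, wd),
    burden = stage_burden(config, wd))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest <- list(
    stage = stage, config = config, seed = seed,
    inputs = stamp_checksums(in_files),
    outputs = stamp_checksums(result$files %||% character(0)),
    elapsed_sec = elapsed,
    version = as.character(utils::packageVersion("habnet")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest,
                       file.path(wd, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  log(sprintf("[habnet] stage %s done in %.1fs", stage, elapsed))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_simulate <- function(config, wd, seed) {
  wc <- world_config(n_lat = config$n_lat %||% 40L,
                     n_lon = config$n_lon %||% 80L,
                     years = config$years %||% 2L,
                     start_year = config$start_year %||% 2023L,
                     effort = config$effort %||% 0.007,
                     seed = seed)
  w <- generate_world(wc)
  paths <- file.path(wd, c("climate", "mask", "population", "truth"))
  write_climate(w$cube, paths[1],
                units = stats::setNames(as.list(rep("degC", 4)),
                                        c("tmean", "tmax", "tmin", "dewpoint")))
  write_land_mask(w$mask, paths[2])
  write_population(w$population, paths[3])
  truth <- climate_cube(w$cube$grid, w$cube$dates,
                        list(habitability = w$habitability))
  write_climate(truth, paths[4])
  obs_path <- file.path(wd, "observations.csv")
  utils::write.csv(data.frame(species = w$observations$species,
                              date = format(w$observations$date),
                              latitude = w$observations$lat,
                              longitude = w$observations$lon),
                   obs_path, row.names = FALSE)
  list(world = w, files = c(obs_path, file.path(paths, "grid.json")))
}

stage_features <- function(config, wd) {
  cube <- read_climate(config$climate)
  derived <- derive_all(cube)
  out <- file.path(wd, "derived")
  write_climate(derived, out)
  list(derived = derived, files = file.path(out, "grid.json"))
}

stage_sample <- function(config, wd, seed) {
  derived <- read_climate(config$derived)
  mask <- read_land_mask(config$mask)
  obs <- read_observations(config$observations, derived$grid,
                           derived$dates, config$seq_len %||% 60L)
  ds <- build_dataset(obs, sampling_config(config$absence_ratio %||% 0.2,
                                           seed = seed),
                      mask, derived, config$seq_len %||% 60L)
  out <- file.path(wd, "dataset.rds")
  saveRDS(ds, out)
  list(dataset = ds, files = out)
}

stage_train <- function(config, wd, seed) {
  derived <- read_climate(config$derived)
  mask <- read_land_mask(config$mask)
  seq_len <- config$seq_len %||% 60L
  obs <- read_observations(config$observations, derived$grid,
                           derived$dates, seq_len)
  ds <- build_dataset(obs, sampling_config(config$absence_ratio %||% 0.2,
                                           seed = seed),
                      mask, derived, seq_len)
  cfg <- model_config(seed = seed, seq_len = seq_len,
                      max_epochs = config$max_epochs %||% 1000L,
                      batch_size = config$batch_size %||% 256L,
                      hidden_sizes = config$hidden_sizes %||% c(128L, 64L, 32L),
                      learning_rate = config$learning_rate %||% 0.001,
                      patience_final = config$patience_final %||% 100L,
                      patience_cv = config$patience_cv %||% 10L)
  split <- if (identical(config$split, "chronological"))
    split_chronological(ds, seed = seed) else split_random(ds, seed = seed)
  model <- train_full(split$train, cfg)
  test_auc <- roc_auc(predict_scores(model, split$test$features),
                      split$test$labels)
  out <- file.path(wd, "model.rds")
  save_model(model, out)
  list(model = model, test_auc = test_auc, files = out)
}

stage_predict <- function(config, wd) {
  model <- load_model(config$model)
  derived <- read_climate(config$derived)
  dates <- as.Date(unlist(config$dates))
  if (length(dates) == 2) dates <- seq(dates[1], dates[2], by = "day")
  raw <- predict_stack(model, derived, dates)
  stack <- risk_map_stack(derived$grid, dates,
                          calibrate_map(raw, model$calibration))
  out <- file.path(wd, "fnr")
  write_risk_maps(stack, out, "geotiff")
  write_risk_maps(stack, file.path(wd, "fnr.csv"), "csv")
  list(stack = stack, files = c(file.path(out, "grid.json"),
                                file.path(wd, "fnr.csv")))
}

stage_calibrate <- function(config, wd) {
  model <- load_model(config$model)
  raw <- read_risk_maps(config$raw_scores)  # raw-score stack on disk
  stack <- risk_map_stack(raw$grid, raw$dates,
                          calibrate_map(raw$fnr, model$calibration))
  out <- file.path(wd, "fnr_recalibrated")
  write_risk_maps(stack, out, "geotiff")
  list(stack = stack, files = file.path(out, "grid.json"))
}

stage_ablate <- function(config, wd, seed) {
  derived <- read_climate(config$derived)
  mask <- read_land_mask(config$mask)
  seq_lens <- as.integer(unlist(config$seq_lens %||% c(30L, 60L)))
  obs <- read_observations(config$observations, derived$grid,
                           derived$dates, max(seq_lens))
  res <- ablation(obs, mask, derived,
                  seq_lens = seq_lens,
                  splits = unlist(config$splits %||% "random"),
                  config = model_config(seed = seed,
                                        max_epochs = config$max_epochs %||% 100L),
                  sampling = sampling_config(seed = seed),
                  max_out = max(as.integer(unlist(config$leave_out %||% c(1L, 2L)))))
  out <- file.path(wd, "ablation.csv")
  utils::write.csv(res, out, row.names = FALSE)
  list(result = res, files = out)
}

stage_compare <- function(config, wd) {
  a <- read_risk_maps(config$map_a)
  b <- read_risk_maps(config$map_b)
  thr <- as.numeric(unlist(config$thresholds %||% seq(0.1, 0.9, by = 0.1)))
  jm <- jaccard_matrix(period_average(a), period_average(b), thr)
  out <- file.path(wd, "jaccard.csv")
  utils::write.csv(jm, out)
  list(matrix = jm, files = out)
}

stage_season <- function(config, wd) {
  stack <- read_risk_maps(config$fnr)
  prof <- season_profile(stack, config$year %||%
                           as.integer(format(stack$dates[1], "%Y")),
                         mass = config$mass %||% 0.95)
  out <- file.path(wd, "season")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_sidecar(out, stack$grid)
  for (nm in c("diameter", "seasonality", "midpoint"))
    write_raster_tif(prof[[nm]], file.path(out, paste0(nm, ".tif")),
                     stack$grid)
  ctr <- cell_center(stack$grid, seq_len(n_cells(stack$grid)))
  csv <- file.path(wd, "season.csv")
  utils::write.csv(data.frame(lat = ctr[, "lat"], lon = ctr[, "lon"],
                              diameter = as.vector(prof$diameter),
                              seasonality = as.vector(prof$seasonality),
                              midpoint = as.vector(prof$midpoint)),
                   csv, row.names = FALSE)
  list(profile = prof, files = c(file.path(out, "grid.json"), csv))
}

stage_burden <- function(config, wd) {
  stacks <- lapply(config$fnr_dirs, read_risk_maps)
  names(stacks) <- vapply(stacks, function(s)
    format(s$dates[1], "%Y"), character(1))
  pop <- resample_population(read_population(config$population),
                             stacks[[1]]$grid)
  years <- as.integer(unlist(config$years))
  if (length(years) == 2 && years[2] > years[1] + 1)
    years <- years[1]:years[2]
  masks <- list(global = NULL)
  for (rg in config$regions %||% list())
    masks[[rg$name]] <- region_box_mask(stacks[[1]]$grid,
                                        unlist(rg$lat), unlist(rg$lon))
  rows <- list(); fits <- list()
  for (nm in names(masks)) {
    bs <- burden_series(stacks, pop, years,
                        threshold = config$threshold %||% 0.5,
                        region_mask = masks[[nm]], region = nm)
    bs$region <- nm
    rows[[nm]] <- bs
    if (nrow(bs) >= 3) fits[[nm]] <- fit_trend(bs)
  }
  series <- do.call(rbind, rows)
  out <- file.path(wd, "burden.csv")
  utils::write.csv(series, out, row.names = FALSE)
  fit_json <- file.path(wd, "burden_trends.json")
  jsonlite::write_json(lapply(fits, function(f)
    list(slope = f$slope, intercept = f$intercept, level = f$level)),
    fit_json, auto_unbox = TRUE, digits = NA)
  list(series = series, trends = fits, files = c(out, fit_json))
}
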