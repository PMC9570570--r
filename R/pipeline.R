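# YAML-configured pipeline driver: simulate -> split -> train -> ensemble
# -> importance -> grid, with a provenance manifest (file checksums).

RUN_CONFIG_FIELDS <- list(
  out_dir = "character", seed = "numeric", stages = "character",
  sensor = "character", speed = "character", labelled = "numeric",
  n_samples = "numeric", n_replicates = "numeric",
  method = "character", epochs = "numeric", batch_size = "numeric",
  learning_rate = "numeric", latent_dim = "numeric",
  n_models = "numeric", n_repeats = "numeric",
  grid_methods = "character", grid_speeds = "character",
  confidence_threshold = "numeric")

#' Validate a pipeline run configuration
#'
#' Checks field names against the published schema (unknown keys are
#' rejected), types, and value ranges, then fills defaults.
#'
#' @param config Named list (e.g. from [yaml::read_yaml()]).
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required")
  unknown <- setdiff(names(config), names(RUN_CONFIG_FIELDS))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (f in names(config)) {
    ok <- switch(RUN_CONFIG_FIELDS[[f]],
                 character = is.character(config[[f]]),
                 numeric = is.numeric(config[[f]]))
    if (!ok) stop("config field '", f, "' must be ",
                  RUN_CONFIG_FIELDS[[f]])
  }
  defaults <- list(seed = 1, stages = c("simulate", "split", "train"),
                   sensor = "both", speed = "medium", labelled = 0,
                   n_samples = 2, n_replicates = 2, method = "tl",
                   epochs = 50, batch_size = 32, learning_rate = 0.001,
                   latent_dim = 16, n_models = 5, n_repeats = 3,
                   grid_methods = c("tl", "combined"),
                   grid_speeds = "medium", confidence_threshold = 0.8)
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  if (!config$labelled %in% c(0, 1))
    stop("config field 'labelled' must be 0 or 1")
  if (!config$sensor %in% SENSOR_TAGS)
    stop("config field 'sensor' must be one of: ",
         paste(SENSOR_TAGS, collapse = ", "))
  if (!config$speed %in% c("slow", "medium", "fast"))
    stop("config field 'speed' must be slow, medium or fast")
  if (!config$method %in% c("tl", "dann", "sgan", "combined"))
    stop("config field 'method' must be tl, dann, sgan or combined")
  bad <- setdiff(config$stages,
                 c("simulate", "split", "train", "ensemble", "importance",
                   "grid"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config
}

#' Run the spectral domain-adaptation pipeline
#'
#' Executes the requested stages in order — `simulate` (write the paired
#' stationary/moving CSV tables and a JSON sidecar of generator truth),
#' `split` (build and manifest the domain split), `train` (fit one model,
#' save it, report test accuracy), `ensemble` (ensemble + confidence and
#' misclassification reports), `importance` (per-wavelength CSV and
#' ranked ranges CSV), `grid` (experiment grid CSV/JSON) — and writes an
#' artifact manifest with an MD5 checksum per file. Later stages reuse the
#' earlier stages' in-memory results, so `split` requires `simulate`,
#' and `train`/`ensemble`/`importance` require `split`.
#'
#' @param config Path to a YAML file or a named list; see
#'   [validate_run_config()] for the schema.
#' @return Invisible list with `status` (0 on success), `manifest`
#'   (data frame of files and checksums) and `results` (key numbers per
#'   stage).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  results <- list(seed = config$seed)
  emit <- function(path) files <<- c(files, path)
  ctl <- da_control(batch_size = config$batch_size,
                    learning_rate = config$learning_rate,
                    epochs = config$epochs, latent_dim = config$latent_dim,
                    seed = config$seed)
  lib <- NULL; pair <- NULL; split <- NULL; fit <- NULL; ens <- NULL

  if ("simulate" %in% config$stages) {
    lib <- material_library(config$seed)
    pair <- simulate_domain_pair(lib, config$speed,
                                 n_samples = config$n_samples,
                                 n_replicates = config$n_replicates,
                                 sensor = config$sensor,
                                 seed = config$seed)
    p_st <- file.path(config$out_dir, "static.csv")
    p_mv <- file.path(config$out_dir, "moving.csv")
    write_spectra_table(pair$static, p_st); emit(p_st)
    write_spectra_table(pair$moving, p_mv); emit(p_mv)
    sidecar <- file.path(config$out_dir, "generator_params.json")
    jsonlite::write_json(
      list(seed = config$seed, speed = config$speed,
           shift = unclass(motion_shift()),
           units = lapply(lib, function(u)
             u[c("material_id", "brand_id", "allergen_class",
                 "baseline_intercept", "baseline_slope")])),
      sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    emit(sidecar)
    results$n_spectra_per_condition <- n_spectra(pair$static)
  }
  if ("split" %in% config$stages) {
    if (is.null(pair)) stop("stage 'split' requires stage 'simulate'")
    split <- make_domain_split(pair$static, pair$moving,
                               n_labelled_per_unit = config$labelled,
                               seed = config$seed)
    p <- file.path(config$out_dir, "split_manifest.json")
    write_split_manifest(split, p); emit(p)
    results$split_sizes <- c(source = n_spectra(split$source_labelled),
                             labelled = n_spectra(split$target_labelled),
                             unlabelled = n_spectra(split$target_unlabelled),
                             test = n_spectra(split$target_test))
  }
  if ("train" %in% config$stages) {
    if (is.null(split)) stop("stage 'train' requires stage 'split'")
    fit <- da_train(split, config$method, ctl)
    p <- file.path(config$out_dir, "model.rds")
    saveRDS(fit, p); emit(p)
    p <- file.path(config$out_dir, "loss_history.csv")
    utils::write.csv(fit$loss_history, p, row.names = FALSE); emit(p)
    results$test_accuracy <- accuracy(predict(fit, split$target_test),
                                      split$target_test$meta$allergen_class)
  }
  if ("ensemble" %in% config$stages) {
    if (is.null(split)) stop("stage 'ensemble' requires stage 'split'")
    ens <- da_ensemble(split, config$method, ctl,
                       n_models = config$n_models)
    preds <- predict(ens, split$target_test)
    rep_ <- confidence_report(preds,
                              split$target_test$meta$allergen_class,
                              threshold = config$confidence_threshold)
    p <- file.path(config$out_dir, "confidence_report.csv")
    utils::write.csv(rep_$counts, p); emit(p)
    br <- misclassification_breakdown(preds,
                                      split$target_test$meta$allergen_class,
                                      split$target_test$meta$material_id)
    p <- file.path(config$out_dir, "misclassification_breakdown.csv")
    utils::write.csv(br, p, row.names = FALSE); emit(p)
    p <- file.path(config$out_dir, "ensemble_summary.json")
    jsonlite::write_json(list(overall_accuracy = rep_$overall_accuracy,
                              bins = as.list(rep_$counts["total",
                                                         , drop = TRUE])),
                         p, auto_unbox = TRUE, digits = NA)
    emit(p)
    results$ensemble_accuracy <- rep_$overall_accuracy
  }
  if ("importance" %in% config$stages) {
    predictor <- if (!is.null(ens)) ens else fit
    if (is.null(predictor)) stop("stage 'importance' requires 'train' or ",
                                 "'ensemble'")
    prof <- permutation_importance(predictor, split$target_test,
                                   n_repeats = config$n_repeats,
                                   seed = config$seed)
    p <- file.path(config$out_dir, "importance_profile.csv")
    utils::write.csv(as.data.frame(prof), p, row.names = FALSE); emit(p)
    rng <- extract_important_ranges(prof)
    p <- file.path(config$out_dir, "important_ranges.csv")
    utils::write.csv(rng, p, row.names = FALSE); emit(p)
    results$n_important_ranges <- nrow(rng)
  }
  if ("grid" %in% config$stages) {
    if (is.null(lib)) lib <- material_library(config$seed)
    datasets <- list()
    datasets[[config$sensor]] <- lapply(
      stats::setNames(config$grid_speeds, config$grid_speeds),
      function(sp) simulate_domain_pair(lib, sp,
                                        n_samples = config$n_samples,
                                        n_replicates = config$n_replicates,
                                        sensor = config$sensor,
                                        seed = config$seed))
    grid <- run_experiment_grid(datasets, methods = config$grid_methods,
                                speeds = config$grid_speeds,
                                sensors = config$sensor,
                                labelled = if (config$labelled == 1)
                                  "single" else "none",
                                control = ctl)
    write_grid_results(grid, file.path(config$out_dir, "grid.csv"),
                       file.path(config$out_dir, "grid.json"))
    emit(file.path(config$out_dir, "grid.csv"))
    emit(file.path(config$out_dir, "grid.json"))
    results$grid_cells_ok <- sum(grid$status == "ok")
  }

  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(list(seed = config$seed, stages = config$stages,
                            files = manifest),
                       mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(status = 0L, manifest = manifest, results = results))
}
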