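# End-to-end orchestration: simulate/ingest -> preprocess -> datasets ->
# features -> selection -> regression -> report.

#' Pipeline configuration
#'
#' Validated bundle of every stage's settings. Defaults reproduce the
#' reference protocol: 50 MHz band half-width, OSS threshold 0.8,
#' five-fold cross-validation and an 80/10/10 trial-disjoint split.
#'
#' @param sensors Sensor ids to process.
#' @param placements Antenna placements per sensor.
#' @param trials_per_placement Repeats per placement (default 5).
#' @param sim Template [sim_config()] for the simulator (sensor and seed
#'   are assigned per trial).
#' @param input_dir Optional directory of written trials (each trial a
#'   subdirectory with a `manifest.yaml`); when given, ingestion replaces
#'   simulation.
#' @param f_th_mhz Band half-width in MHz.
#' @param onset_thresh Pressure-onset threshold, mmHg/s.
#' @param hampel_window,hampel_k Cleaning parameters.
#' @param eq3_variant Optimal-frequency reading, see [optimal_frequency()].
#' @param oss_threshold OSS correlation threshold.
#' @param sig_level OSS significance gate.
#' @param model_subset Preset ids to train (default `NULL` = all 25).
#' @param cv_folds Trial-level CV folds (0 skips CV).
#' @param seed Master seed for simulation, splitting and fitting.
#' @param out_dir Optional run directory; when given, every stage output is
#'   serialized there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sensors = sensor_ids(),
                            placements = c("5 mm", "10 mm", "20 mm",
                                           "30 mm", "opposite"),
                            trials_per_placement = 5,
                            sim = sim_config(),
                            input_dir = NULL,
                            f_th_mhz = 50, onset_thresh = 0.1,
                            hampel_window = 11, hampel_k = 3,
                            eq3_variant = "per_bin",
                            oss_threshold = 0.8, sig_level = 0.001,
                            model_subset = NULL, cv_folds = 5,
                            seed = 1L, out_dir = NULL) {
  stopifnot_scalar_number(f_th_mhz, "f_th_mhz", positive = TRUE)
  stopifnot_scalar_number(oss_threshold, "oss_threshold")
  stopifnot_scalar_number(onset_thresh, "onset_thresh", positive = TRUE)
  bad <- setdiff(sensors, sensor_ids())
  if (length(bad)) {
    abort(sprintf("Unknown sensors: %s", paste(bad, collapse = ", ")),
          class = "icp_invalid_config")
  }
  if (!is.null(model_subset)) {
    bad <- setdiff(model_subset, model_registry()$preset_id)
    if (length(bad)) {
      abort(sprintf("Unknown presets: %s", paste(bad, collapse = ", ")),
            class = "icp_invalid_config")
    }
  }
  structure(
    list(sensors = sensors, placements = placements,
         trials_per_placement = trials_per_placement, sim = sim,
         input_dir = input_dir, f_th_mhz = f_th_mhz,
         onset_thresh = onset_thresh, hampel_window = hampel_window,
         hampel_k = hampel_k, eq3_variant = eq3_variant,
         oss_threshold = oss_threshold, sig_level = sig_level,
         model_subset = model_subset, cv_folds = cv_folds,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

ingest_trials <- function(input_dir) {
  manifests <- list.files(input_dir, pattern = "^manifest\\.yaml$",
                          recursive = TRUE, full.names = TRUE)
  if (!length(manifests)) {
    abort(sprintf("No trial manifests under %s.", input_dir),
          class = "icp_io_error")
  }
  lapply(manifests, read_trial)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "icp_stage_error", parent = e)
  })
}

#' Run the full pipeline
#'
#' Executes, per sensor: simulation (or ingestion), alignment and
#' preprocessing of every trial, dataset-variant creation, two-level
#' feature extraction, correlation analysis, ordered feature selection,
#' trial-disjoint splitting, training of the preset zoo and evaluation on
#' the held-out test trials. When the configuration names an output
#' directory, every stage's table is serialized there together with a run
#' manifest (config hash, seed, package version).
#'
#' @param config A [pipeline_config()].
#' @return List of class `icp_run`: `features`, `correlations`,
#'   `bin_counts`, `selection` (per sensor), `metrics`, `evaluation`,
#'   `best` (per-sensor tibble) and `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a `pipeline_config`.",
          class = "icp_invalid_config")
  }
  presets <- model_registry()
  if (!is.null(config$model_subset)) {
    presets <- presets[presets$preset_id %in% config$model_subset, ]
  }
  all_feats <- list(); all_corr <- list(); all_sel <- list()
  all_metrics <- list(); all_eval <- list(); best_rows <- list()
  for (s in config$sensors) {
    trials <- run_stage("simulate", {
      if (is.null(config$input_dir)) {
        simulate_campaign(sensors = s, placements = config$placements,
                          trials_per_placement = config$trials_per_placement,
                          config = config$sim, seed = config$seed)
      } else {
        Filter(function(t) t$sensor_id == s, ingest_trials(config$input_dir))
      }
    })
    feats <- run_stage("features", {
      dplyr::bind_rows(lapply(trials, function(tr) {
        pr <- preprocess_trial(tr, f_th_mhz = config$f_th_mhz,
                               onset_thresh = config$onset_thresh,
                               hampel_window = config$hampel_window,
                               hampel_k = config$hampel_k,
                               eq3_variant = config$eq3_variant)
        extract_features(pr)
      }))
    })
    corr <- run_stage("selection", correlate_features(feats))
    sel <- run_stage("selection",
                     oss_select(corr, threshold = config$oss_threshold,
                                sig_level = config$sig_level))
    chosen <- sel$class[sel$selected]
    if (!length(chosen)) {
      abort(sprintf("Sensor %s: OSS selected no features.", s),
            class = "icp_stage_error")
    }
    fm <- run_stage("regression", feature_matrix(feats, classes = chosen))
    split <- run_stage("regression",
                       split_trials(unique(fm$trial_id), seed = config$seed))
    ms <- run_stage("regression",
                    train_models(fm, split, presets = presets,
                                 cv_folds = config$cv_folds,
                                 seed = config$seed))
    ev <- run_stage("regression", evaluate_models(ms, fm, role = "test"))
    best_id <- select_best(ms$metrics, rmse_col = "val_rmse",
                           mae_col = "val_mae")
    best_test <- ev[ev$preset_id == best_id, ]
    all_feats[[s]] <- feats
    all_corr[[s]] <- corr
    all_sel[[s]] <- dplyr::mutate(sel, sensor_id = s, .before = 1)
    all_metrics[[s]] <- dplyr::mutate(ms$metrics, sensor_id = s, .before = 1)
    all_eval[[s]] <- dplyr::mutate(tidy(ev), sensor_id = s, .before = 1)
    best_rows[[s]] <- tibble::tibble(
      sensor_id = s, best_preset = best_id,
      test_mae = best_test$mae, test_rmse = best_test$rmse,
      test_r2 = best_test$r2)
  }
  out <- structure(
    list(features = dplyr::bind_rows(all_feats),
         correlations = dplyr::bind_rows(all_corr),
         bin_counts = bin_summary(dplyr::bind_rows(all_corr)),
         selection = dplyr::bind_rows(all_sel),
         metrics = dplyr::bind_rows(all_metrics),
         evaluation = dplyr::bind_rows(all_eval),
         best = dplyr::bind_rows(best_rows),
         config = config),
    class = "icp_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$features, file.path(out_dir, "features.csv"))
  readr::write_csv(run$correlations, file.path(out_dir, "correlations.csv"))
  readr::write_csv(run$bin_counts, file.path(out_dir, "bin_counts.csv"))
  readr::write_csv(run$selection, file.path(out_dir, "selection.csv"))
  readr::write_csv(run$metrics, file.path(out_dir, "metrics.csv"))
  readr::write_csv(run$evaluation, file.path(out_dir, "evaluation.csv"))
  readr::write_csv(run$best, file.path(out_dir, "best.csv"))
  cfg <- run$config
  cfg_plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(
    list(schema = "icpsweep-run/1",
         package_version = as.character(utils::packageVersion("icpsweep")),
         seed = cfg$seed,
         config_hash = rlang::hash(cfg_plain),
         config = cfg_plain[setdiff(names(cfg_plain),
                                    c("sim", "out_dir"))]),
    file.path(out_dir, "run_manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.icp_run <- function(x, ...) {
  cat(sprintf("<icp_run> %d sensors, %d feature rows, %d presets\n",
              length(unique(x$best$sensor_id)), nrow(x$features),
              length(unique(x$metrics$preset_id))))
  print(x$best)
  invisible(x)
}
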