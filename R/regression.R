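# Training, cross-validation and evaluation of the preset zoo.

#' Wide per-sweep model matrix from a tidy feature table
#'
#' Pivots the selected feature classes to one column each, one row per
#' (trial, variant, sweep), carrying the reference pressure as the label.
#'
#' @param features Tidy table from [extract_features()].
#' @param classes Feature classes to keep (default: all present).
#' @param variants Variants to keep (default: all present).
#' @return Tibble with `trial_id` (sensor/trial key), `variant`,
#'   `sweep_index`, `p_mmHg` and one column per feature class.
#' @export
feature_matrix <- function(features, classes = NULL, variants = NULL) {
  if (!is.null(classes)) {
    features <- features[features$class %in% classes, ]
  }
  if (!is.null(variants)) {
    features <- features[features$variant %in% variants, ]
  }
  if (!nrow(features)) {
    abort("No feature rows left after filtering.", class = "icp_empty_input")
  }
  features |>
    dplyr::mutate(trial_id = paste(.data$sensor_id, .data$placement,
                                   .data$trial_index, sep = "/")) |>
    dplyr::select("trial_id", "variant", "sweep_index", "p_mmHg",
                  "class", "value") |>
    tidyr::pivot_wider(names_from = "class", values_from = "value") |>
    tidyr::drop_na()
}

metrics_from_pred <- function(pred, truth) {
  resid <- pred - truth
  sst <- sum((truth - mean(truth))^2)
  degenerate <- sst == 0
  r2 <- if (degenerate) 0 else 1 - sum(resid^2) / sst
  tibble::tibble(mae = mean(abs(resid)), rmse = sqrt(mean(resid^2)),
                 r2 = r2, degenerate_sst = degenerate)
}

#' Train the regression presets on the training trials
#'
#' Fits each preset on all sweeps of the training trials and scores it on
#' the validation trials; optionally also runs a trial-level k-fold
#' cross-validation within the training set. Splits are by whole trials, so
#' no sweep of a validation or test trial ever reaches a fit. Presets are
#' fixed: there is no hyperparameter tuning.
#'
#' @param data Model matrix from [feature_matrix()].
#' @param split A `split_assignment` over the `trial_id` values.
#' @param presets Subset of [model_registry()] rows (default: all 25).
#' @param cv_folds Number of trial-level CV folds within training (default
#'   5; 0 skips CV).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fit.
#' @return Object of class `icp_model_set`: fitted predictors, a `metrics`
#'   tibble (training, validation and optional CV columns per preset), the
#'   split and the feature column names.
#' @export
train_models <- function(data, split, presets = model_registry(),
                         cv_folds = 5, seed = 1L) {
  feat_cols <- setdiff(names(data), c("trial_id", "variant", "sweep_index",
                                      "p_mmHg"))
  if (!length(feat_cols)) {
    abort("Empty feature selection.", class = "icp_empty_input")
  }
  train_ids <- split_role(split, "train")
  val_ids <- split_role(split, "validation")
  tr <- data[data$trial_id %in% train_ids, ]
  va <- data[data$trial_id %in% val_ids, ]
  if (!nrow(tr)) abort("No training rows.", class = "icp_empty_input")
  x_tr <- tr[feat_cols]; y_tr <- tr$p_mmHg
  fold_of <- NULL
  if (cv_folds > 0) {
    ids <- unique(tr$trial_id)
    fold_of <- with_fixed_seed(as.integer(seed),
      setNames(sample(rep_len(seq_len(cv_folds), length(ids))), ids))
  }
  fits <- list()
  rows <- list()
  for (i in seq_len(nrow(presets))) {
    pid <- presets$preset_id[[i]]
    fit <- fit_preset(pid, x_tr, y_tr, seed = seed)
    fits[[pid]] <- fit
    m_tr <- metrics_from_pred(fit$predict(x_tr), y_tr)
    m_va <- if (nrow(va)) {
      metrics_from_pred(fit$predict(va[feat_cols]), va$p_mmHg)
    } else {
      tibble::tibble(mae = NA_real_, rmse = NA_real_, r2 = NA_real_,
                     degenerate_sst = NA)
    }
    cv <- tibble::tibble(cv_mae = NA_real_, cv_rmse = NA_real_)
    if (cv_folds > 0) {
      preds <- rep(NA_real_, nrow(tr))
      for (fold in seq_len(cv_folds)) {
        hold <- fold_of[tr$trial_id] == fold
        if (!any(hold) || all(hold)) next
        f <- fit_preset(pid, x_tr[!hold, , drop = FALSE], y_tr[!hold],
                        seed = seed)
        preds[hold] <- f$predict(x_tr[hold, , drop = FALSE])
      }
      ok <- !is.na(preds)
      if (any(ok)) {
        cv <- tibble::tibble(cv_mae = mean(abs(preds[ok] - y_tr[ok])),
                             cv_rmse = sqrt(mean((preds[ok] - y_tr[ok])^2)))
      }
    }
    rows[[i]] <- tibble::tibble(
      no = presets$no[[i]], preset_id = pid, label = presets$label[[i]],
      family = presets$family[[i]],
      train_mae = m_tr$mae, train_rmse = m_tr$rmse, train_r2 = m_tr$r2,
      val_mae = m_va$mae, val_rmse = m_va$rmse, val_r2 = m_va$r2,
      cv_mae = cv$cv_mae, cv_rmse = cv$cv_rmse)
  }
  structure(list(fits = fits, metrics = dplyr::bind_rows(rows),
                 split = split, train_ids = train_ids,
                 feat_cols = feat_cols, seed = seed),
            class = "icp_model_set")
}

#' @export
print.icp_model_set <- function(x, ...) {
  cat(sprintf("<icp_model_set> %d presets on %d features (%s)\n",
              length(x$fits), length(x$feat_cols),
              paste(x$feat_cols, collapse = ", ")))
  invisible(x)
}

#' Evaluate fitted presets on held-out trials
#'
#' Predicts pressure on the sweeps of the trials holding `role` in the
#' model set's split and reports MAE, RMSE and R-squared per preset
#' together with the residual series. Refuses any overlap between the
#' requested trials and the training trials (leakage guard).
#'
#' @param model_set An `icp_model_set`.
#' @param data Model matrix containing the held-out trials.
#' @param role Which split role to evaluate (default `"test"`).
#' @return Tibble of class `icp_eval`: per preset `mae`, `rmse`, `r2`
#'   (mmHg-scale metrics), `n_obs`, plus list-columns `predicted` and
#'   `residuals` and the prediction throughput `pred_speed_obs_s`
#'   (informational).
#' @export
evaluate_models <- function(model_set, data, role = "test") {
  ids <- split_role(model_set$split, role)
  # Guard against the ids actually fitted, not the split's current labels.
  train_ids <- model_set$train_ids %||% split_role(model_set$split, "train")
  if (role != "train" && length(intersect(ids, train_ids))) {
    abort("Evaluation trials overlap training trials.",
          class = "icp_leakage_error")
  }
  te <- data[data$trial_id %in% ids, ]
  if (!nrow(te)) abort("No rows for the requested role.",
                       class = "icp_empty_input")
  x_te <- te[model_set$feat_cols]
  rows <- lapply(names(model_set$fits), function(pid) {
    fit <- model_set$fits[[pid]]
    t0 <- proc.time()[["elapsed"]]
    pred <- fit$predict(x_te)
    dt <- proc.time()[["elapsed"]] - t0
    m <- metrics_from_pred(pred, te$p_mmHg)
    tibble::tibble(preset_id = pid, mae = m$mae, rmse = m$rmse, r2 = m$r2,
                   degenerate_sst = m$degenerate_sst, n_obs = nrow(te),
                   pred_speed_obs_s = if (dt > 0) nrow(te) / dt else NA_real_,
                   predicted = list(pred),
                   residuals = list(pred - te$p_mmHg))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(model_registry()[c("no", "preset_id", "label", "family")],
                     by = "preset_id") |>
    dplyr::relocate("no", "preset_id", "label", "family") |>
    dplyr::arrange(.data$no)
  class(out) <- c("icp_eval", class(out))
  out
}

#' Best-performing preset of an evaluation or validation report
#'
#' Lowest RMSE; ties resolved by lower MAE, then registry order.
#'
#' @param report Tibble with `preset_id`, `rmse`, `mae` (e.g. an
#'   `icp_eval`, or the `metrics` of an `icp_model_set` using the
#'   validation columns).
#' @param rmse_col,mae_col Column names to rank on.
#' @return The `preset_id` of the winner.
#' @export
select_best <- function(report, rmse_col = "rmse", mae_col = "mae") {
  if (!nrow(report)) abort("Empty report.", class = "icp_empty_input")
  ord <- order(report[[rmse_col]], report[[mae_col]],
               match(report$preset_id, model_registry()$preset_id))
  report$preset_id[[ord[1]]]
}

#' @export
tidy.icp_model_set <- function(x, ...) x$metrics

#' @export
glance.icp_model_set <- function(x, ...) {
  best <- select_best(x$metrics, rmse_col = "val_rmse", mae_col = "val_mae")
  row <- x$metrics[x$metrics$preset_id == best, ]
  tibble::tibble(n_presets = nrow(x$metrics),
                 n_features = length(x$feat_cols),
                 best_preset = best,
                 best_val_rmse = row$val_rmse, best_val_mae = row$val_mae)
}

#' @export
tidy.icp_eval <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"predicted", -"residuals")
}
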