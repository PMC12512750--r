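#' Write a trial to disk (Touchstone sweeps + reference CSV + manifest)
#'
#' Serializes one trial as the package's interchange layout: one two-port
#' Touchstone `.s2p` file per sweep (dB/angle, GHz), the reference stream as
#' a CSV with header `time_s,p_mmHg,t_C`, and a YAML manifest recording
#' sensor, placement, grid, sweep rate, file list and the trigger pairs.
#'
#' @param trial An `icp_trial`.
#' @param directory Output directory; created if missing.
#' @return Path to the written manifest (invisibly usable by
#'   [read_trial()]).
#' @export
write_trial <- function(trial, directory) {
  if (!inherits(trial, "icp_trial")) {
    abort("`trial` must be an `icp_trial`.", class = "icp_io_error")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    abort(sprintf("Cannot create directory %s.", directory),
          class = "icp_io_error")
  }
  n_sweeps <- nrow(trial$sxx_mag)
  sweep_files <- sprintf("sweep_%04d.s2p", seq_len(n_sweeps))
  for (k in seq_len(n_sweeps)) {
    write_touchstone(
      file.path(directory, sweep_files[[k]]),
      trial$grid$freq,
      trial$sxx_mag[k, ], trial$sxx_phase[k, ],
      trial$sxy_mag[k, ], trial$sxy_phase[k, ],
      comment = sprintf("sensor %s trial %d sweep %d t=%.6f s",
                        trial$sensor_id, trial$trial_index, k,
                        trial$time[[k]]))
  }
  readr::write_csv(trial$reference[c("time_s", "p_mmHg", "t_C")],
                   file.path(directory, "reference.csv"))
  manifest <- list(
    format = "icpsweep-trial/1",
    sensor_id = trial$sensor_id,
    trial_index = trial$trial_index,
    placement = trial$placement,
    sweep_rate_hz = trial$sweep_rate_hz,
    grid = list(f_start = trial$grid$f_start, f_stop = trial$grid$f_stop,
                n_points = trial$grid$n_points),
    reference_file = "reference.csv",
    sweeps = lapply(seq_len(n_sweeps), function(k) {
      list(file = sweep_files[[k]], time_s = trial$time[[k]])
    }),
    triggers = lapply(seq_len(nrow(trial$triggers)), function(k) {
      list(sweep_index = trial$triggers$sweep_index[[k]],
           ref_time_s = trial$triggers$ref_time_s[[k]])
    })
  )
  manifest_path <- file.path(directory, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path, precision = 15)
  invisible(manifest_path)
}

#' Read a trial written by [write_trial()]
#'
#' @param manifest_path Path to a trial manifest (`manifest.yaml`).
#' @return An `icp_trial`. Phases come back unwrapped along frequency.
#' @export
read_trial <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("Manifest not found: %s", manifest_path),
          class = "icp_io_error")
  }
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  grid <- freq_grid(man$grid$f_start, man$grid$f_stop, man$grid$n_points)
  n_sweeps <- length(man$sweeps)
  n_f <- grid$n_points
  sxx_mag <- sxx_phase <- sxy_mag <- sxy_phase <- matrix(0, n_sweeps, n_f)
  times <- numeric(n_sweeps)
  for (k in seq_len(n_sweeps)) {
    entry <- man$sweeps[[k]]
    f <- file.path(base, entry$file)
    if (!file.exists(f)) {
      abort(sprintf("Sweep file listed in manifest is missing: %s",
                    entry$file), class = "icp_io_error")
    }
    sw <- read_touchstone(f)
    if (length(sw$freq_ghz) != n_f ||
        max(abs(sw$freq_ghz - grid$freq)) > 1e-6) {
      abort(sprintf(
        "Frequency grid of %s (%d points) does not match the manifest grid (%d points).",
        entry$file, length(sw$freq_ghz), n_f), class = "icp_format_error")
    }
    sxx_mag[k, ] <- sw$sxx_mag
    sxx_phase[k, ] <- sw$sxx_phase
    sxy_mag[k, ] <- sw$sxy_mag
    sxy_phase[k, ] <- sw$sxy_phase
    times[[k]] <- entry$time_s
  }
  reference <- readr::read_csv(file.path(base, man$reference_file),
                               show_col_types = FALSE)
  if (!all(c("time_s", "p_mmHg", "t_C") %in% names(reference))) {
    abort("Reference CSV must have columns time_s, p_mmHg, t_C.",
          class = "icp_format_error")
  }
  triggers <- tibble::tibble(
    sweep_index = vapply(man$triggers, function(x) as.integer(x$sweep_index),
                         integer(1)),
    ref_time_s = vapply(man$triggers, function(x) as.numeric(x$ref_time_s),
                        numeric(1))
  )
  new_icp_trial(
    sensor_id = man$sensor_id, trial_index = as.integer(man$trial_index),
    placement = man$placement, grid = grid,
    sweep_rate_hz = man$sweep_rate_hz, time = times,
    sxx_mag = sxx_mag, sxx_phase = sxx_phase,
    sxy_mag = sxy_mag, sxy_phase = sxy_phase,
    reference = reference, triggers = triggers
  )
}

#' Synchronize a trial's sweeps with its reference pressure stream
#'
#' Each sweep integrates over its acquisition interval, so its reference
#' pressure is taken as the mean of the reference stream over a window of
#' one sweep period centred at the sweep's trigger timestamp (not the
#' nearest sample, which would alias the pulsatile component).
#'
#' @param trial An `icp_trial` with a trigger entry per sweep and a
#'   reference stream sampled at or above the sweep rate.
#' @return The trial with `pressure` and `temperature` vectors (one value
#'   per sweep) filled in.
#' @export
align_reference <- function(trial) {
  if (!inherits(trial, "icp_trial")) {
    abort("`trial` must be an `icp_trial`.", class = "icp_sync_error")
  }
  n_sweeps <- nrow(trial$sxx_mag)
  trig <- trial$triggers
  missing <- setdiff(seq_len(n_sweeps), trig$sweep_index)
  if (length(missing)) {
    abort(sprintf("No trigger entry for frame %s.",
                  paste(missing, collapse = ", ")),
          class = "icp_sync_error")
  }
  half <- 0.5 / trial$sweep_rate_hz
  rt <- trial$reference$time_s
  rp <- trial$reference$p_mmHg
  rc <- trial$reference$t_C
  p_out <- t_out <- numeric(n_sweeps)
  for (k in seq_len(n_sweeps)) {
    t0 <- trig$ref_time_s[trig$sweep_index == k][[1]]
    sel <- rt >= t0 - half - 1e-12 & rt <= t0 + half + 1e-12
    if (!any(sel)) {
      abort(sprintf("Reference stream has no samples in the window of frame %d.",
                    k), class = "icp_sync_error")
    }
    p_out[[k]] <- mean(rp[sel])
    t_out[[k]] <- mean(rc[sel])
  }
  trial$pressure <- p_out
  trial$temperature <- t_out
  trial
}
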