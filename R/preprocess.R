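# Cleaning, optimal-band selection and time limiting.

#' Hampel outlier filter with truncated edge windows
#'
#' Flags sample i as an outlier when it deviates from the median of its
#' centred window by more than `k` scaled median absolute deviations
#' (MAD, consistency constant 1.4826) and replaces it by that window
#' median. Windows are truncated at the series edges so every sample is
#' screened.
#'
#' @param x Numeric series.
#' @param window Full window length (odd, default 11).
#' @param k MAD multiplier (default 3).
#' @return List with `values` (outliers replaced), `outliers` (logical
#'   mask) and the inputs' length.
#' @export
hampel_filter <- function(x, window = 11, k = 3) {
  if (!length(x)) abort("Empty series.", class = "icp_empty_input")
  n <- length(x)
  h <- floor(window / 2)
  out <- x
  mask <- logical(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    med <- median(x[j])
    mad_s <- 1.4826 * median(abs(x[j] - med))
    if (abs(x[i] - med) > k * mad_s) {
      out[i] <- med
      mask[i] <- TRUE
    }
  }
  list(values = out, outliers = mask, n = n)
}

#' Clean and normalize one data string
#'
#' The first preprocessing stage applied independently to every data string
#' (the temporal series of one frequency bin of one channel): Hampel outlier
#' replacement followed by z-score normalization. Zero-variance strings map
#' to all-zeros rather than dividing by zero.
#'
#' @param x Numeric series (one data string).
#' @param window,k Hampel parameters, see [hampel_filter()].
#' @return List with `normalized`, `cleaned` (outlier-replaced raw values),
#'   `outliers`, `center`, `scale`.
#' @examples
#' zeta1_clean(c(0, 0, 0, 100, 0, 0, 0))$outliers
#' @export
zeta1_clean <- function(x, window = 11, k = 3) {
  hf <- hampel_filter(x, window = window, k = k)
  ctr <- mean(hf$values)
  scl <- sd(hf$values)
  if (!is.finite(scl) || scl == 0) {
    normalized <- rep(0, length(x))
    scl <- 0
  } else {
    normalized <- (hf$values - ctr) / scl
  }
  list(normalized = normalized, cleaned = hf$values, outliers = hf$outliers,
       center = ctr, scale = scl)
}

# Apply zeta1 column-wise (per frequency bin) to a sweeps-by-bins matrix.
zeta1_clean_matrix <- function(m, window = 11, k = 3) {
  cleaned <- normalized <- m
  outliers <- matrix(FALSE, nrow(m), ncol(m))
  centers <- scales <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    z <- zeta1_clean(m[, j], window = window, k = k)
    cleaned[, j] <- z$cleaned
    normalized[, j] <- z$normalized
    outliers[, j] <- z$outliers
    centers[[j]] <- z$center
    scales[[j]] <- z$scale
  }
  list(cleaned = cleaned, normalized = normalized, outliers = outliers,
       center = centers, scale = scales)
}

#' Per-sweep location and value of the magnitude minimum
#'
#' @param frames Sweeps-by-bins magnitude matrix (dB).
#' @param freq Frequency axis (GHz), one value per column.
#' @return Tibble with `sweep_index`, `loc_GHz`, `val_db`; ties broken
#'   toward the lowest frequency.
#' @export
locate_minima <- function(frames, freq) {
  if (!nrow(frames)) abort("No frames.", class = "icp_empty_input")
  idx <- apply(frames, 1, argmin_first)
  tibble::tibble(sweep_index = seq_len(nrow(frames)),
                 loc_GHz = freq[idx],
                 val_db = frames[cbind(seq_len(nrow(frames)), idx)])
}

#' Frequency of maximal temporal variation
#'
#' Scans every frequency bin for the temporal range (max minus min across
#' sweeps) of the magnitude and returns the bin where that range peaks —
#' the centre of the band that carries the pressure information. Ties break
#' toward the lowest frequency. The alternative reading `variant =
#' "located"` takes the range of the per-sweep minimum values grouped by
#' their located bin; it is undefined when no bin hosts two minima.
#'
#' @param frames Sweeps-by-bins magnitude matrix (dB).
#' @param freq Frequency axis (GHz).
#' @param variant `"per_bin"` (default) or `"located"`.
#' @return Scalar frequency `f_opt` (GHz).
#' @export
optimal_frequency <- function(frames, freq, variant = c("per_bin", "located")) {
  variant <- match.arg(variant)
  if (nrow(frames) < 2) {
    abort("Need at least two frames.", class = "icp_empty_input")
  }
  if (variant == "per_bin") {
    rng <- apply(frames, 2, function(col) max(col) - min(col))
    if (max(rng) <= 0) {
      abort("All bins are temporally constant; no optimal frequency.",
            class = "icp_degenerate_input")
    }
    freq[argmax_first(rng)]
  } else {
    mins <- locate_minima(frames, freq)
    by_loc <- split(mins$val_db, mins$loc_GHz)
    by_loc <- by_loc[vapply(by_loc, length, integer(1)) >= 2]
    if (!length(by_loc)) {
      abort("No frequency bin hosts repeated minima; 'located' variant undefined.",
            class = "icp_degenerate_input")
    }
    locs <- as.numeric(names(by_loc))
    rng <- vapply(by_loc, function(v) max(v) - min(v), numeric(1))
    if (max(rng) <= 0) {
      abort("Per-bin minima ranges all zero.", class = "icp_degenerate_input")
    }
    cand <- locs[rng >= max(rng) - 1e-15]
    min(cand)
  }
}

#' Optimal band around the optimal frequency
#'
#' Closed interval `[f_opt - f_th, f_opt + f_th]` intersected with the
#' grid; the half-width default of 50 MHz captures the significant spectral
#' features while keeping downstream computation light.
#'
#' @param f_opt Centre frequency (GHz), on the grid.
#' @param grid A [freq_grid()].
#' @param f_th_mhz Half-width in MHz (default 50).
#' @return List of class `band_selection`: `f_opt`, `f_th_mhz`, `f_lo`,
#'   `f_hi` (GHz, clipped to the grid) and member `bins` (column indices).
#' @export
optimal_band <- function(f_opt, grid, f_th_mhz = 50) {
  stopifnot_scalar_number(f_th_mhz, "f_th_mhz", positive = TRUE)
  f_th <- f_th_mhz / 1000
  f_lo <- max(grid$f_start, f_opt - f_th)
  f_hi <- min(grid$f_stop, f_opt + f_th)
  bins <- which(grid$freq >= f_lo - 1e-12 & grid$freq <= f_hi + 1e-12)
  structure(list(f_opt = f_opt, f_th_mhz = f_th_mhz, f_lo = f_lo,
                 f_hi = f_hi, bins = bins),
            class = "band_selection")
}

# Onset of pressure change: first sweep whose centred slope estimate of the
# aligned pressure exceeds the threshold (one-sided differences at edges).
pressure_onset <- function(p, time, thresh = 0.1) {
  n <- length(p)
  if (n < 3) abort("Too few sweeps.", class = "icp_empty_input")
  slope <- numeric(n)
  slope[1] <- (p[2] - p[1]) / (time[2] - time[1])
  slope[n] <- (p[n] - p[n - 1]) / (time[n] - time[n - 1])
  mid <- 2:(n - 1)
  slope[mid] <- (p[mid + 1] - p[mid - 1]) / (time[mid + 1] - time[mid - 1])
  idx <- which(slope > thresh)
  if (!length(idx)) {
    abort("Pressure never changes faster than the onset threshold.",
          class = "icp_degenerate_input")
  }
  idx[[1]]
}

#' Band- and time-limit an aligned trial
#'
#' The second preprocessing stage: restricts all four channel matrices to
#' the optimal band and to the active time window — sweeps from the
#' detected pressure onset up to the sweep where pressure first reaches its
#' maximum. Pre-onset sweeps are retained separately as the quiet baseline
#' used by the differential (MDM) features.
#'
#' @param trial An aligned `icp_trial` (see [align_reference()]), with
#'   channels already cleaned (see [preprocess_trial()] for the packaged
#'   composition).
#' @param band A `band_selection` from [optimal_band()].
#' @param onset_thresh Onset slope threshold in mmHg/s (default 0.1).
#' @return List with the limited channel matrices, `pressure`, `time`,
#'   `retained` (absolute sweep indices), `band` and `baseline` (pre-onset
#'   band-limited frames, possibly zero rows).
#' @export
zeta2_limit <- function(trial, band, onset_thresh = 0.1) {
  if (is.null(trial$pressure)) {
    abort("Trial must be aligned before time limiting.",
          class = "icp_sync_error")
  }
  onset <- pressure_onset(trial$pressure, trial$time, onset_thresh)
  i_max <- which(trial$pressure >= max(trial$pressure) - 1e-12)[[1]]
  if (i_max < onset) i_max <- length(trial$pressure)
  keep <- onset:i_max
  bins <- band$bins
  pre <- if (onset > 1) seq_len(onset - 1) else integer(0)
  list(
    sxx_mag = trial$sxx_mag[keep, bins, drop = FALSE],
    sxx_phase = trial$sxx_phase[keep, bins, drop = FALSE],
    sxy_mag = trial$sxy_mag[keep, bins, drop = FALSE],
    sxy_phase = trial$sxy_phase[keep, bins, drop = FALSE],
    pressure = trial$pressure[keep],
    time = trial$time[keep],
    retained = keep,
    band = band,
    baseline = list(
      sxx_mag = trial$sxx_mag[pre, bins, drop = FALSE],
      sxy_mag = trial$sxy_mag[pre, bins, drop = FALSE]
    )
  )
}

#' Full preprocessing of an aligned trial
#'
#' Composes the pipeline's preprocessing stages: per-bin cleaning and
#' normalization of all four channels, per-sweep minima of the reflection
#' magnitude, optimal-frequency and optimal-band selection from the
#' reflection channel (the single band is applied to all channels), and
#' band/time limiting. Phases are unwrapped along frequency before any
#' phase-derived computation.
#'
#' @param trial An aligned `icp_trial`.
#' @param f_th_mhz Band half-width in MHz.
#' @param onset_thresh Onset slope threshold, mmHg/s.
#' @param hampel_window,hampel_k Cleaning parameters.
#' @param eq3_variant Reading of the maximal-deviation statistic, see
#'   [optimal_frequency()].
#' @return An object of class `icp_processed`: metadata, the limited
#'   channel matrices (cleaned dB / unwrapped rad), `pressure`, `time`,
#'   `band`, `minima` (per-sweep tibble), `normalization` (per channel:
#'   centers, scales, outlier counts) and `baseline` frames for
#'   differential features.
#' @export
preprocess_trial <- function(trial, f_th_mhz = 50, onset_thresh = 0.1,
                             hampel_window = 11, hampel_k = 3,
                             eq3_variant = c("per_bin", "located")) {
  eq3_variant <- match.arg(eq3_variant)
  if (is.null(trial$pressure)) trial <- align_reference(trial)
  channels <- c("sxx_mag", "sxx_phase", "sxy_mag", "sxy_phase")
  norm_rec <- list()
  cleaned <- trial
  for (ch in channels) {
    m <- trial[[ch]]
    if (grepl("phase", ch)) m <- t(apply(m, 1, unwrap_phase))
    z <- zeta1_clean_matrix(m, window = hampel_window, k = hampel_k)
    cleaned[[ch]] <- z$cleaned
    norm_rec[[ch]] <- list(center = z$center, scale = z$scale,
                           n_outliers = sum(z$outliers))
  }
  minima <- locate_minima(cleaned$sxx_mag, trial$grid$freq)
  f_opt <- optimal_frequency(cleaned$sxx_mag, trial$grid$freq,
                             variant = eq3_variant)
  band <- optimal_band(f_opt, trial$grid, f_th_mhz = f_th_mhz)
  lim <- zeta2_limit(cleaned, band, onset_thresh = onset_thresh)
  structure(
    list(sensor_id = trial$sensor_id, trial_index = trial$trial_index,
         placement = trial$placement, grid = trial$grid,
         freq = trial$grid$freq[band$bins],
         sxx_mag = lim$sxx_mag, sxx_phase = lim$sxx_phase,
         sxy_mag = lim$sxy_mag, sxy_phase = lim$sxy_phase,
         pressure = lim$pressure, time = lim$time, retained = lim$retained,
         band = band, minima = minima, normalization = norm_rec,
         baseline = lim$baseline),
    class = "icp_processed"
  )
}

#' @export
print.icp_processed <- function(x, ...) {
  cat(sprintf(
    "<icp_processed> sensor %s trial %d: %d sweeps, band %.4g-%.4g GHz (%d bins)\n",
    x$sensor_id, x$trial_index, length(x$pressure), x$band$f_lo, x$band$f_hi,
    length(x$band$bins)))
  invisible(x)
}

#' Average repeated trials with the standard error of the mean
#'
#' Element-wise mean across repeated trials of one sensor/placement cell,
#' with per-element SEM (`sd / sqrt(n)`). Trials of unequal length are
#' truncated to the shortest; supplying fewer than the customary five
#' repeats triggers a warning and proceeds with the flagged smaller `n`.
#'
#' @param trials List of `icp_processed` objects of one sensor/placement.
#' @param expected_n Customary number of repeats (default 5).
#' @return List with `mean` (channel matrices and pressure), `sem` (same
#'   shapes) and `n`.
#' @export
average_trials <- function(trials, expected_n = 5) {
  if (!length(trials)) abort("No trials.", class = "icp_empty_input")
  sensors <- unique(vapply(trials, `[[`, character(1), "sensor_id"))
  placements <- unique(vapply(trials, `[[`, character(1), "placement"))
  if (length(sensors) > 1 || length(placements) > 1) {
    abort("Trials mix sensors or placements; cannot average.",
          class = "icp_invalid_config")
  }
  n <- length(trials)
  if (n != expected_n) {
    warn(sprintf("Averaging %d trials (expected %d).", n, expected_n))
  }
  len <- min(vapply(trials, function(t) length(t$pressure), integer(1)))
  nb <- min(vapply(trials, function(t) ncol(t$sxx_mag), integer(1)))
  fields <- c("sxx_mag", "sxx_phase", "sxy_mag", "sxy_phase")
  mean_out <- sem_out <- list()
  for (f in fields) {
    arr <- vapply(trials, function(t) t[[f]][seq_len(len), seq_len(nb)],
                  matrix(0, len, nb))
    mean_out[[f]] <- apply(arr, c(1, 2), mean)
    sem_out[[f]] <- apply(arr, c(1, 2), sd) / sqrt(n)
  }
  pm <- vapply(trials, function(t) t$pressure[seq_len(len)], numeric(len))
  mean_out$pressure <- rowMeans(pm)
  sem_out$pressure <- apply(pm, 1, sd) / sqrt(n)
  list(mean = mean_out, sem = sem_out, n = n)
}
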