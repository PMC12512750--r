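# Two-level per-sweep feature extraction over the optimal band.
#
# Level 1 descriptors (extrema with locations, area under the curve) are
# applied to the four band-limited channel curves directly; Level 2 applies
# the same descriptors to derived quantities: the differential multistatic
# data matrix (MDM_D), its RMS reduction over the band, group delay
# distortion (GDD) and percent amplitude of fluctuation (PerAF). Appendix-
# level formulas for the derived quantities follow the standard literature
# definitions and are documented with each function.

#' Curve extrema with located frequencies
#'
#' @param curve Numeric curve over the band.
#' @param freq Frequency axis (GHz), same length.
#' @return List with `min`, `min_loc`, `max`, `max_loc`; ties toward the
#'   lowest frequency.
#' @export
level1_extrema <- function(curve, freq) {
  if (!length(curve)) abort("Empty curve.", class = "icp_empty_input")
  i_min <- argmin_first(curve)
  i_max <- argmax_first(curve)
  list(min = curve[i_min], min_loc = freq[i_min],
       max = curve[i_max], max_loc = freq[i_max])
}

#' Area under a band-limited curve
#'
#' Trapezoidal integral over the band's frequency axis (GHz times the
#' curve's unit).
#'
#' @param curve Numeric curve (>= 2 points).
#' @param freq Frequency axis (GHz).
#' @return Scalar area.
#' @export
band_auc <- function(curve, freq) {
  if (length(curve) < 2) {
    abort("AUC needs at least two points.", class = "icp_empty_input")
  }
  pracma::trapz(freq, curve)
}

#' Differential multistatic-data-matrix curve per sweep
#'
#' Forms, per sweep and frequency bin, the symmetric two-port dB-magnitude
#' matrix `[[Sxx, Sxy], [Sxy, Sxx]]`, subtracts the element-wise mean of
#' the baseline frames, and reduces each bin to a scalar by the Frobenius
#' norm scaled by `1/sqrt(2)` — so a step of `d` dB confined to one
#' measured channel maps to exactly `|d|`. With both channels measured the
#' reduction equals `sqrt(dSxx^2 + dSxy^2)`.
#'
#' @param sxx_mag,sxy_mag Sweeps-by-bins magnitude matrices (dB).
#' @param baseline Optional list with pre-onset `sxx_mag` / `sxy_mag`
#'   frames; when absent or empty, the first `baseline_count` sweeps serve
#'   as baseline.
#' @param baseline_count Number of leading sweeps used when no pre-onset
#'   baseline is available (default 5).
#' @return Sweeps-by-bins matrix of differential norms.
#' @export
mdm_d <- function(sxx_mag, sxy_mag, baseline = NULL, baseline_count = 5) {
  use_internal <- is.null(baseline) || !nrow(baseline$sxx_mag)
  if (use_internal) {
    if (nrow(sxx_mag) < baseline_count + 1) {
      abort(sprintf("Need more than %d frames for an internal MDM baseline.",
                    baseline_count), class = "icp_empty_input")
    }
    base_xx <- colMeans(sxx_mag[seq_len(baseline_count), , drop = FALSE])
    base_xy <- colMeans(sxy_mag[seq_len(baseline_count), , drop = FALSE])
  } else {
    nb <- nrow(baseline$sxx_mag)
    take <- max(1, nb - baseline_count + 1):nb
    base_xx <- colMeans(baseline$sxx_mag[take, , drop = FALSE])
    base_xy <- colMeans(baseline$sxy_mag[take, , drop = FALSE])
  }
  dxx <- sweep(sxx_mag, 2, base_xx)
  dxy <- sweep(sxy_mag, 2, base_xy)
  sqrt(dxx^2 + dxy^2)
}

#' RMS reduction of the MDM curve over the band
#'
#' @param mdm Sweeps-by-bins matrix from [mdm_d()].
#' @return One scalar per sweep.
#' @export
mdm_rms <- function(mdm) {
  if (!ncol(mdm)) abort("Empty band.", class = "icp_empty_input")
  sqrt(rowMeans(mdm^2))
}

#' Group delay distortion of a phase curve
#'
#' Group delay is the negative frequency derivative of the unwrapped phase,
#' `tau(f) = -(1/2 pi) dphi/df` (central differences; one-sided at the band
#' edges). Distortion is the deviation of the delay from its band mean, so
#' any frequency-flat delay (linear phase) maps to zero.
#'
#' @param phase Unwrapped phase curve (rad) over the band (>= 3 points).
#' @param freq Frequency axis (GHz).
#' @return List with `tau` (delay curve, ns), `distortion` (delay minus its
#'   band mean) and `auc_abs` (trapezoidal area of `|distortion|`, the
#'   scalar feature).
#' @export
gdd <- function(phase, freq) {
  if (length(phase) < 3) {
    abort("Group delay needs at least 3 points.", class = "icp_empty_input")
  }
  phase <- unwrap_phase(phase)
  if (any(abs(diff(phase)) > pi)) {
    warn("Phase jumps exceed pi after unwrapping; group delay may be aliased.")
  }
  n <- length(phase)
  dphi <- numeric(n)
  dphi[1] <- (phase[2] - phase[1]) / (freq[2] - freq[1])
  dphi[n] <- (phase[n] - phase[n - 1]) / (freq[n] - freq[n - 1])
  mid <- 2:(n - 1)
  dphi[mid] <- (phase[mid + 1] - phase[mid - 1]) / (freq[mid + 1] - freq[mid - 1])
  tau <- -dphi / (2 * pi)
  distortion <- tau - mean(tau)
  list(tau = tau, distortion = distortion,
       auc_abs = pracma::trapz(freq, abs(distortion)))
}

#' Percent amplitude of fluctuation of a band-limited curve
#'
#' Mean absolute deviation of the curve from its band mean, expressed as a
#' percentage of the absolute band mean: `100 * mean(|x - mu|) / |mu|`.
#' Scale-invariant for positive scalings; undefined (NA) when the band
#' mean is zero.
#'
#' @param curve Numeric curve over the band.
#' @return Scalar percentage, or NA for a zero-mean curve.
#' @export
peraf <- function(curve) {
  if (!length(curve)) abort("Empty curve.", class = "icp_empty_input")
  mu <- mean(curve)
  if (mu == 0) return(NA_real_)
  100 * mean(abs(curve - mu)) / abs(mu)
}

# Moving trapezoidal area over time of a scalar series, centred window of
# `width` sweeps, truncated at the edges.
moving_auc_time <- function(x, time, width = 5) {
  h <- floor(width / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    pracma::trapz(time[j], x[j])
  }, numeric(1))
}

#' The 12 feature classes
#'
#' @return Tibble mapping class ids `a`..`l` to their level, source channel
#'   and transform.
#' @export
feature_classes <- function() {
  tibble::tribble(
    ~class, ~level, ~channel,     ~transform,
    "a",    1L,     "|S_XX|",     "min",
    "b",    1L,     "|S_XY|",     "min",
    "c",    1L,     "|S_XX|",     "auc",
    "d",    1L,     "|S_XY|",     "auc",
    "e",    2L,     "angle S_XX", "auc_gdd",
    "f",    2L,     "angle S_XY", "auc_gdd",
    "g",    2L,     "MDM_D",      "auc",
    "h",    2L,     "MDM_RMS",    "moving_auc",
    "i",    2L,     "|S_XX|",     "peraf",
    "j",    2L,     "|S_XY|",     "peraf",
    "k",    2L,     "angle S_XX", "peraf",
    "l",    2L,     "angle S_XY", "peraf"
  )
}

#' Extract the 12 feature classes for the variants of one processed trial
#'
#' Computes, per sweep of each dataset variant, the 12 per-sweep feature
#' series: band minima of both magnitude channels (a, b), band AUC of both
#' magnitude channels (c, d), AUC of the absolute group delay distortion of
#' both phase channels (e, f), AUC over frequency of the differential MDM
#' curve (g), a 5-sweep moving AUC over time of the RMS-reduced MDM (h),
#' and PerAF of the magnitude and phase channels (i--l). Each value is
#' aligned with the sweep's reference pressure.
#'
#' @param processed An `icp_processed`.
#' @param variants Variant table from [create_variants()]; defaults to all
#'   four.
#' @param baseline_count MDM baseline depth, see [mdm_d()].
#' @return Tidy tibble: `sensor_id`, `trial_index`, `placement`, `variant`,
#'   `class`, `level`, `channel`, `sweep_index` (absolute within the
#'   processed trial), `time_s`, `value`, `loc_GHz` (located frequency for
#'   extremum classes, else NA) and `p_mmHg`.
#' @export
extract_features <- function(processed, variants = create_variants(processed),
                             baseline_count = 5) {
  freq <- processed$freq
  n <- length(processed$pressure)
  # Per-sweep primitives computed once over the full processed trial.
  mins_xx <- locate_minima(processed$sxx_mag, freq)
  mins_xy <- locate_minima(processed$sxy_mag, freq)
  auc_rows <- function(m) apply(m, 1, band_auc, freq = freq)
  gdd_rows <- function(m) apply(m, 1, function(ph) gdd(ph, freq)$auc_abs)
  peraf_rows <- function(m) apply(m, 1, peraf)
  mdm <- mdm_d(processed$sxx_mag, processed$sxy_mag,
               baseline = processed$baseline,
               baseline_count = baseline_count)
  rms_series <- mdm_rms(mdm)
  full <- list(
    a = list(value = mins_xx$val_db, loc = mins_xx$loc_GHz),
    b = list(value = mins_xy$val_db, loc = mins_xy$loc_GHz),
    c = list(value = auc_rows(processed$sxx_mag)),
    d = list(value = auc_rows(processed$sxy_mag)),
    e = list(value = gdd_rows(processed$sxx_phase)),
    f = list(value = gdd_rows(processed$sxy_phase)),
    g = list(value = auc_rows(mdm)),
    h = list(value = moving_auc_time(rms_series, processed$time)),
    i = list(value = peraf_rows(processed$sxx_mag)),
    j = list(value = peraf_rows(processed$sxy_mag)),
    k = list(value = peraf_rows(processed$sxx_phase)),
    l = list(value = peraf_rows(processed$sxy_phase))
  )
  classes <- feature_classes()
  purrr::pmap_dfr(variants, function(variant, k, a, b, n_sweeps) {
    idx <- a:b
    purrr::pmap_dfr(classes, function(class, level, channel, transform) {
      v <- full[[class]]
      tibble::tibble(
        sensor_id = processed$sensor_id,
        trial_index = processed$trial_index,
        placement = processed$placement,
        variant = variant,
        class = class, level = level, channel = channel,
        sweep_index = idx,
        time_s = processed$time[idx],
        value = v$value[idx],
        loc_GHz = if (is.null(v$loc)) NA_real_ else v$loc[idx],
        p_mmHg = processed$pressure[idx]
      )
    })
  })
}
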