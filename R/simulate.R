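#' Pressure-coupling model of a simulated sensor
#'
#' Describes how intracranial pressure perturbs the sensor's two-port
#' response. Rising pressure changes the effective dielectric profile under
#' the antennas, which the simulator represents with three linear couplings:
#' an amplitude offset concentrated near the resonance (a Gaussian bump), a
#' resonance-frequency shift, and a phase offset. The magnitudes are
#' synthetic simulator parameters — the physical mechanism is published, the
#' coefficients are not — with defaults strong enough that pressure-tracking
#' features are clearly planted relative to the default trace noise.
#'
#' @param alpha_mag_db Amplitude coupling at resonance, dB per mmHg.
#' @param beta_freq_mhz Resonance shift, MHz per mmHg.
#' @param gamma_phase_rad Phase offset, rad per mmHg.
#' @param bump_width_mhz Standard deviation (MHz) of the Gaussian spectral
#'   shape carrying the amplitude coupling, centred at the resonance.
#'
#' @return A list of class `coupling_model`.
#' @examples
#' coupling_model()                      # planted defaults
#' coupling_model(0, 0, 0)               # null coupling: baseline passthrough
#' @export
coupling_model <- function(alpha_mag_db = -0.05, beta_freq_mhz = 0.1,
                           gamma_phase_rad = 0.002, bump_width_mhz = 50) {
  stopifnot_scalar_number(alpha_mag_db, "alpha_mag_db")
  stopifnot_scalar_number(beta_freq_mhz, "beta_freq_mhz")
  stopifnot_scalar_number(gamma_phase_rad, "gamma_phase_rad")
  stopifnot_scalar_number(bump_width_mhz, "bump_width_mhz", positive = TRUE)
  structure(list(alpha_mag_db = alpha_mag_db, beta_freq_mhz = beta_freq_mhz,
                 gamma_phase_rad = gamma_phase_rad,
                 bump_width_mhz = bump_width_mhz),
            class = "coupling_model")
}

#' Configuration of one simulated phantom trial
#'
#' Bundles everything [simulate_trial()] needs: the frequency grid, the
#' sensor profile, the pressure coupling, the trajectory parameters, the
#' sweep rate and the instrument noise floor. Defaults follow the reference
#' measurement protocol: 2--6 GHz at 2001 points, 3 Hz sweep rate, 5 kHz
#' reference sampling, a 0 to 60 mmHg ramp at 60 beats per minute, and an
#' RMS trace noise of 5e-3 dB.
#'
#' @param sensor_id One of [sensor_ids()].
#' @param grid A [freq_grid()].
#' @param coupling A [coupling_model()].
#' @param duration_s,lead_s,p_max,pulse_rate,pulse_amp,ref_rate_hz,t_C
#'   Trajectory parameters, see [pressure_trajectory()].
#' @param sweep_rate_hz Sweeps per second of the analyser (default 3).
#' @param trace_noise_db RMS additive Gaussian noise on magnitude traces, dB.
#' @param seed Integer RNG seed; identical configurations yield identical
#'   trials.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sensor_id = "A", grid = freq_grid(),
                       coupling = coupling_model(),
                       duration_s = 120, lead_s = 10, p_max = 60,
                       pulse_rate = 60, pulse_amp = 2, ref_rate_hz = 5000,
                       t_C = 23, sweep_rate_hz = 3, trace_noise_db = 5e-3,
                       seed = 1L) {
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(sweep_rate_hz, "sweep_rate_hz", positive = TRUE)
  stopifnot_scalar_number(trace_noise_db, "trace_noise_db")
  if (trace_noise_db < 0) {
    abort("`trace_noise_db` must be >= 0.", class = "icp_invalid_config")
  }
  structure(
    list(sensor_id = sensor_id, grid = grid, coupling = coupling,
         duration_s = duration_s, lead_s = lead_s, p_max = p_max,
         pulse_rate = pulse_rate, pulse_amp = pulse_amp,
         ref_rate_hz = ref_rate_hz, t_C = t_C,
         sweep_rate_hz = sweep_rate_hz, trace_noise_db = trace_noise_db,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Reference trajectory implied by a simulation configuration
#'
#' @param config A [sim_config()].
#' @return See [pressure_trajectory()].
#' @export
make_pressure_trajectory <- function(config) {
  pressure_trajectory(duration_s = config$duration_s, lead_s = config$lead_s,
                      p_max = config$p_max, pulse_rate = config$pulse_rate,
                      pulse_amp = config$pulse_amp,
                      ref_rate_hz = config$ref_rate_hz, t_C = config$t_C)
}

#' Forward-simulate one pressure-coupled measurement trial
#'
#' Generates the sweep sequence of a single trial: at each sweep time the
#' baseline profile is shifted in frequency by `beta_freq_mhz * p(t)`,
#' offset in magnitude by `alpha_mag_db * p(t)` times a Gaussian spectral
#' shape centred at the resonance, and offset in phase by
#' `gamma_phase_rad * p(t)`; independent Gaussian noise with the configured
#' RMS is added to both magnitude traces. Sweeps are timestamped at the
#' centre of their acquisition window and paired with the reference stream
#' through a trigger log.
#'
#' @param config A [sim_config()].
#' @param trial_index Trial number within its sensor/placement cell.
#' @param placement Antenna placement label, one of
#'   `"5 mm"`, `"10 mm"`, `"20 mm"`, `"30 mm"`, `"opposite"`.
#'
#' @return An object of class `icp_trial`: sensor/placement metadata, the
#'   frequency grid, sweep times, four sweeps-by-frequency matrices
#'   (`sxx_mag`, `sxx_phase`, `sxy_mag`, `sxy_phase`), the reference
#'   trajectory, the trigger table and the true per-sweep pressure
#'   (`p_true`, simulator ground truth; alignment against the reference
#'   stream is a separate, estimated quantity).
#' @examples
#' cfg <- sim_config(duration_s = 5, lead_s = 1, ref_rate_hz = 200,
#'                   grid = freq_grid(n_points = 101))
#' tr <- simulate_trial(cfg)
#' nrow(tr$sxx_mag)  # floor(duration * sweep_rate)
#' @export
simulate_trial <- function(config, trial_index = 1L, placement = "10 mm") {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a `sim_config`.", class = "icp_invalid_config")
  }
  profile <- sensor_profile(config$sensor_id, config$grid)
  cp <- config$coupling
  max_shift <- abs(cp$beta_freq_mhz) / 1000 * config$p_max
  if (profile$resonance_f0 + max_shift > config$grid$f_stop ||
      profile$resonance_f0 - max_shift < config$grid$f_start) {
    abort("Coupling shifts the resonance outside the frequency grid.",
          class = "icp_invalid_config")
  }
  n_sweeps <- floor(config$duration_s * config$sweep_rate_hz)
  if (n_sweeps < 1) {
    abort("Configuration yields no sweeps.", class = "icp_invalid_config")
  }
  sweep_times <- (seq_len(n_sweeps) - 0.5) / config$sweep_rate_hz
  p_true <- trajectory_pressure_at(sweep_times, config$duration_s,
                                   config$lead_s, config$p_max,
                                   config$pulse_rate, config$pulse_amp)$total

  f <- config$grid$freq
  n_f <- length(f)
  sd_bump <- cp$bump_width_mhz / 1000
  bump_shape <- exp(-(f - profile$resonance_f0)^2 / (2 * sd_bump^2))

  shift_curve <- function(base, shift) {
    if (shift == 0) return(base)
    approx(f, base, xout = f - shift, rule = 2)$y
  }

  with_fixed_seed(config$seed, {
    traj <- make_pressure_trajectory(config)
    sxx_mag <- sxy_mag <- sxx_phase <- sxy_phase <-
      matrix(0, n_sweeps, n_f)
    for (k in seq_len(n_sweeps)) {
      p <- p_true[k]
      shift <- cp$beta_freq_mhz / 1000 * p
      bump <- cp$alpha_mag_db * p * bump_shape
      dphi <- cp$gamma_phase_rad * p
      sxx_mag[k, ] <- shift_curve(profile$baseline_sxx, shift) + bump
      sxy_mag[k, ] <- shift_curve(profile$baseline_sxy, shift) + bump
      sxx_phase[k, ] <- shift_curve(profile$baseline_phase_sxx, shift) + dphi
      sxy_phase[k, ] <- shift_curve(profile$baseline_phase_sxy, shift) + dphi
    }
    if (config$trace_noise_db > 0) {
      sxx_mag <- sxx_mag +
        matrix(rnorm(n_sweeps * n_f, 0, config$trace_noise_db), n_sweeps, n_f)
      sxy_mag <- sxy_mag +
        matrix(rnorm(n_sweeps * n_f, 0, config$trace_noise_db), n_sweeps, n_f)
    }
    new_icp_trial(
      sensor_id = config$sensor_id, trial_index = as.integer(trial_index),
      placement = placement, grid = config$grid,
      sweep_rate_hz = config$sweep_rate_hz,
      time = sweep_times,
      sxx_mag = sxx_mag, sxx_phase = sxx_phase,
      sxy_mag = sxy_mag, sxy_phase = sxy_phase,
      reference = traj,
      triggers = tibble::tibble(sweep_index = seq_len(n_sweeps),
                                ref_time_s = sweep_times),
      p_true = p_true
    )
  })
}

new_icp_trial <- function(sensor_id, trial_index, placement, grid,
                          sweep_rate_hz, time, sxx_mag, sxx_phase,
                          sxy_mag, sxy_phase, reference, triggers,
                          p_true = NULL, pressure = NULL,
                          temperature = NULL) {
  structure(
    list(sensor_id = sensor_id, trial_index = trial_index,
         placement = placement, grid = grid, sweep_rate_hz = sweep_rate_hz,
         time = time, sxx_mag = sxx_mag, sxx_phase = sxx_phase,
         sxy_mag = sxy_mag, sxy_phase = sxy_phase, reference = reference,
         triggers = triggers, p_true = p_true, pressure = pressure,
         temperature = temperature),
    class = "icp_trial"
  )
}

#' @export
print.icp_trial <- function(x, ...) {
  cat(sprintf(
    "<icp_trial> sensor %s, trial %d, placement %s: %d sweeps x %d bins%s\n",
    x$sensor_id, x$trial_index, x$placement, nrow(x$sxx_mag),
    ncol(x$sxx_mag), if (is.null(x$pressure)) "" else " (aligned)"))
  invisible(x)
}

#' Flatten a trial's sweeps to a long tibble
#'
#' @param x An `icp_trial`.
#' @param ... Unused.
#' @return Tibble with one row per (sweep, frequency bin): `sweep_index`,
#'   `time_s`, `freq_GHz`, `sxx_mag_db`, `sxx_phase_rad`, `sxy_mag_db`,
#'   `sxy_phase_rad` and, when aligned, `p_mmHg`.
#' @export
as_tibble.icp_trial <- function(x, ...) {
  n_sweeps <- nrow(x$sxx_mag)
  n_f <- ncol(x$sxx_mag)
  out <- tibble::tibble(
    sweep_index = rep(seq_len(n_sweeps), each = n_f),
    time_s = rep(x$time, each = n_f),
    freq_GHz = rep(x$grid$freq, times = n_sweeps),
    sxx_mag_db = as.vector(t(x$sxx_mag)),
    sxx_phase_rad = as.vector(t(x$sxx_phase)),
    sxy_mag_db = as.vector(t(x$sxy_mag)),
    sxy_phase_rad = as.vector(t(x$sxy_phase))
  )
  if (!is.null(x$pressure)) {
    out$p_mmHg <- rep(x$pressure, each = n_f)
  }
  out
}

#' Simulate a multi-placement measurement campaign for one or more sensors
#'
#' Runs [simulate_trial()] over every combination of sensor, antenna
#' placement and repeat, mirroring the reference protocol of five repeated
#' trials in each of five placements (25 trials per sensor). Each trial gets
#' a distinct seed derived from `seed`.
#'
#' @param sensors Character vector of sensor ids.
#' @param placements Character vector of placement labels.
#' @param trials_per_placement Repeats per (sensor, placement) cell.
#' @param config Template [sim_config()]; its sensor and seed are overridden
#'   per trial.
#' @param seed Campaign-level integer seed.
#'
#' @return A list of `icp_trial` objects.
#' @export
simulate_campaign <- function(sensors = sensor_ids(),
                              placements = c("5 mm", "10 mm", "20 mm",
                                             "30 mm", "opposite"),
                              trials_per_placement = 5,
                              config = sim_config(), seed = 1L) {
  trials <- list()
  idx <- 0L
  for (s in sensors) {
    for (d in placements) {
      for (j in seq_len(trials_per_placement)) {
        idx <- idx + 1L
        cfg <- config
        cfg$sensor_id <- s
        cfg$seed <- (as.integer(seed) * 10007L + idx * 211L) %% 2147483647L
        trials[[idx]] <- simulate_trial(
          cfg,
          trial_index = (match(d, placements) - 1L) * trials_per_placement + j,
          placement = d)
      }
    }
  }
  trials
}
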