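# Shared fixtures: small, fast simulated trials built in code.

small_grid <- function(n_points = 201) freq_grid(2, 6, n_points)

quick_config <- function(duration_s = 15, lead_s = 3, ref_rate_hz = 200,
                         pulse_amp = 1, grid = small_grid(), seed = 1L,
                         ...) {
  sim_config(duration_s = duration_s, lead_s = lead_s,
             ref_rate_hz = ref_rate_hz, pulse_amp = pulse_amp,
             grid = grid, seed = seed, ...)
}

quick_trial <- function(..., seed = 1L) {
  align_reference(simulate_trial(quick_config(..., seed = seed)))
}

quick_processed <- function(..., seed = 1L) {
  preprocess_trial(quick_trial(..., seed = seed))
}

# A bare aligned trial with prescribed per-sweep pressure and flat unit
# spectra; used to exercise time-limiting and alignment logic directly.
flat_trial <- function(pressure, time = seq_along(pressure), n_f = 12,
                       sweep_rate_hz = 1) {
  n <- length(pressure)
  m <- matrix(1, n, n_f)
  icpsweep:::new_icp_trial(
    sensor_id = "A", trial_index = 1L, placement = "10 mm",
    grid = freq_grid(2, 6, n_f), sweep_rate_hz = sweep_rate_hz,
    time = time, sxx_mag = m, sxx_phase = m, sxy_mag = m, sxy_phase = m,
    reference = tibble::tibble(time_s = time, p_mmHg = pressure,
                               t_C = rep(23, n)),
    triggers = tibble::tibble(sweep_index = seq_len(n), ref_time_s = time),
    pressure = pressure
  )
}
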