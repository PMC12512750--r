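#' Reference pressure/temperature trajectory of a pumping trial
#'
#' Models the invasive reference stream of one measurement trial: a leading
#' flat segment before the dosing pump starts, then a linear filling ramp
#' from 0 mmHg to `p_max` superposed with a zero-mean pulsatile component at
#' the pump beat rate, sampled at the reference rate.
#'
#' The pulsatile component is a smooth sinusoidal beat, active only while
#' the pump runs. It is zero-mean over every whole beat (the ramp alone
#' carries the trend, and the mean over a beat equals the ramp value at the
#' beat centre) and zero-valued at beat boundaries, so the trajectory
#' starts the pumping phase and ends the trial exactly on the ramp.
#'
#' @param duration_s Total trial duration in seconds.
#' @param lead_s Flat pre-pump segment length in seconds (< `duration_s`).
#' @param p_max Terminal ramp pressure in mmHg (default 60).
#' @param pulse_rate Pump rate in beats per minute (default 60).
#' @param pulse_amp Peak-to-peak pulsatile amplitude in mmHg.
#' @param ref_rate_hz Reference sampling rate in Hz (default 5000).
#' @param t_C Phantom temperature in degrees Celsius.
#'
#' @return A tibble of class `icp_trajectory` with columns `time_s`,
#'   `p_mmHg`, `t_C` plus attributes `ramp` (the pulsation-free component)
#'   and the generating parameters.
#' @examples
#' traj <- pressure_trajectory(duration_s = 10, lead_s = 2, ref_rate_hz = 100)
#' max(traj$p_mmHg)
#' @export
pressure_trajectory <- function(duration_s = 120, lead_s = 10, p_max = 60,
                                pulse_rate = 60, pulse_amp = 2,
                                ref_rate_hz = 5000, t_C = 23) {
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(p_max, "p_max", positive = TRUE)
  stopifnot_scalar_number(pulse_rate, "pulse_rate", positive = TRUE)
  stopifnot_scalar_number(ref_rate_hz, "ref_rate_hz", positive = TRUE)
  stopifnot_scalar_number(lead_s, "lead_s")
  if (lead_s < 0 || lead_s >= duration_s) {
    abort("`lead_s` must lie in [0, duration_s).", class = "icp_invalid_config")
  }
  times <- seq(0, duration_s, by = 1 / ref_rate_hz)
  p <- trajectory_pressure_at(times, duration_s, lead_s, p_max,
                              pulse_rate, pulse_amp)
  out <- tibble::tibble(time_s = times, p_mmHg = p$total,
                        t_C = rep(t_C, length(times)))
  attr(out, "ramp") <- p$ramp
  attr(out, "params") <- list(duration_s = duration_s, lead_s = lead_s,
                              p_max = p_max, pulse_rate = pulse_rate,
                              pulse_amp = pulse_amp, ref_rate_hz = ref_rate_hz,
                              t_C = t_C)
  class(out) <- c("icp_trajectory", class(out))
  out
}

# Pointwise evaluation shared by the reference stream and the sweep sampler.
trajectory_pressure_at <- function(t, duration_s, lead_s, p_max,
                                   pulse_rate, pulse_amp) {
  ramp_span <- duration_s - lead_s
  ramp <- pmin(pmax((t - lead_s) / ramp_span, 0), 1) * p_max
  beat_hz <- pulse_rate / 60
  pulse <- ifelse(t >= lead_s & t <= duration_s,
                  (pulse_amp / 2) * sin(2 * pi * beat_hz * (t - lead_s)),
                  0)
  list(ramp = ramp, total = ramp + pulse)
}
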