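#' Sensor identifiers known to the simulator
#'
#' @return Character vector `c("A", ..., "F")`.
#' @export
sensor_ids <- function() c("A", "B", "C", "D", "E", "F")

# Per-sensor resonance parameters. Dip locations and depths follow the
# published frequency responses of the six sensors; dip widths (GHz) and
# baseline levels (dB) are smooth-profile parameters chosen to reproduce
# those printed minima on the standard grid.
sensor_profile_params <- function() {
  list(
    A = list(sxx = list(base = -10, dips = list(list(f0 = 3.565, depth = -35.3, w = 0.08))),
             sxy = list(base = -24, dips = list(list(f0 = 3.565, depth = -31.84, w = 0.12)))),
    B = list(sxx = list(base = -12, dips = list(list(f0 = 3.658, depth = -25.31, w = 0.55))),
             sxy = list(base = -35, dips = list(list(f0 = 3.604, depth = -65.87, w = 0.05)))),
    C = list(sxx = list(base = -8,  dips = list(list(f0 = 2.886, depth = -15,    w = 0.18))),
             sxy = list(base = -35, dips = list(list(f0 = 4.5,   depth = -50,    w = 0.35)))),
    D = list(sxx = list(base = -10, dips = list(list(f0 = 3.21,  depth = -22.83, w = 0.40))),
             sxy = list(base = -33, dips = list(list(f0 = 3.5,   depth = -38,    w = 0.30)))),
    E = list(sxx = list(base = -9,  dips = list(list(f0 = 3.8,   depth = -20,    w = 0.30))),
             sxy = list(base = -38, dips = list(list(f0 = 3.8,   depth = -44,    w = 0.30)))),
    F = list(sxx = list(base = -12, dips = list(list(f0 = 4.4,   depth = -35,    w = 0.25))),
             sxy = list(base = -28, dips = list(list(f0 = 3.9,   depth = -33,    w = 0.30))))
  )
}

# Lorentzian dip evaluated on `f`; equals 1 at f0.
lorentz <- function(f, f0, w) 1 / (1 + ((f - f0) / w)^2)

# Magnitude curve: flat baseline carved by Lorentzian dips. Each dip centre
# is snapped onto the grid so the sampled global minimum sits exactly at a
# grid point with exactly the requested depth.
resonance_curve <- function(grid, base, dips) {
  y <- rep(base, grid$n_points)
  for (d in dips) {
    f0 <- grid_snap(grid, d$f0)
    y <- y + (d$depth - base) * lorentz(grid$freq, f0, d$w)
  }
  y
}

#' Baseline S-parameter profile of a simulated sensor
#'
#' Builds the noise-free, zero-pressure two-port response of one of the six
#' sensor designs: reflection (`S_XX`) and transmission (`S_XY`) magnitude
#' curves with Lorentzian resonance dips at the sensors' published
#' frequencies, plus smooth unwrapped phase curves combining a linear
#' electrical-delay term with a resonance phase signature.
#'
#' @param sensor_id One of `sensor_ids()`.
#' @param grid A [freq_grid()]; dip centres are snapped to its points.
#'
#' @return An object of class `sensor_profile`: list with `sensor_id`,
#'   `grid`, magnitude curves `baseline_sxx` / `baseline_sxy` (dB), unwrapped
#'   phase curves `baseline_phase_sxx` / `baseline_phase_sxy` (rad) and the
#'   grid-snapped reflection resonance `resonance_f0` (GHz).
#' @examples
#' prof <- sensor_profile("A")
#' prof$resonance_f0
#' min(prof$baseline_sxx)
#' @export
sensor_profile <- function(sensor_id, grid = freq_grid()) {
  pars <- sensor_profile_params()
  if (!is.character(sensor_id) || length(sensor_id) != 1 ||
      !sensor_id %in% names(pars)) {
    abort(sprintf("Unknown sensor id %s; expected one of %s.",
                  deparse(sensor_id), paste(sensor_ids(), collapse = ", ")),
          class = "icp_unknown_sensor")
  }
  p <- pars[[sensor_id]]
  f <- grid$freq
  f0 <- grid_snap(grid, p$sxx$dips[[1]]$f0)
  # Electrical delays (ns): linear phase slope -2*pi*tau*f for f in GHz.
  tau_xx <- 1.5
  tau_xy <- 2.0
  phase_res <- function(f0, w) -2 * atan((f - f0) / w)
  structure(
    list(
      sensor_id = sensor_id,
      grid = grid,
      baseline_sxx = resonance_curve(grid, p$sxx$base, p$sxx$dips),
      baseline_sxy = resonance_curve(grid, p$sxy$base, p$sxy$dips),
      baseline_phase_sxx = -2 * pi * tau_xx * f +
        phase_res(f0, p$sxx$dips[[1]]$w),
      baseline_phase_sxy = -2 * pi * tau_xy * f +
        phase_res(grid_snap(grid, p$sxy$dips[[1]]$f0), p$sxy$dips[[1]]$w),
      resonance_f0 = f0
    ),
    class = "sensor_profile"
  )
}

#' @export
print.sensor_profile <- function(x, ...) {
  cat(sprintf("<sensor_profile %s> resonance %.4g GHz, min Sxx %.4g dB\n",
              x$sensor_id, x$resonance_f0, min(x$baseline_sxx)))
  invisible(x)
}
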