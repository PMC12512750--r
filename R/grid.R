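#' Uniform frequency grid for a vector-network-analyser sweep
#'
#' Constructs the frequency axis shared by every sweep of a trial. The
#' default matches the instrument setting assumed throughout the package:
#' a calibrated 2--6 GHz sweep sampled at 2001 points (2 MHz spacing).
#'
#' @param f_start Sweep start frequency in GHz.
#' @param f_stop Sweep stop frequency in GHz; must exceed `f_start`.
#' @param n_points Number of uniformly spaced frequency points (>= 2).
#'
#' @return An object of class `freq_grid`: a list with `f_start`, `f_stop`,
#'   `n_points`, the point vector `freq` (GHz) and the spacing `step` (GHz).
#' @examples
#' g <- freq_grid()
#' g$n_points
#' head(g$freq)
#' @export
freq_grid <- function(f_start = 2, f_stop = 6, n_points = 2001) {
  stopifnot_scalar_number(f_start, "f_start")
  stopifnot_scalar_number(f_stop, "f_stop")
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 2 ||
      n_points != as.integer(n_points)) {
    abort("`n_points` must be an integer >= 2.", class = "icp_invalid_config")
  }
  if (f_start >= f_stop) {
    abort("`f_start` must be strictly below `f_stop`.",
          class = "icp_invalid_config")
  }
  n_points <- as.integer(n_points)
  freq <- seq(f_start, f_stop, length.out = n_points)
  structure(
    list(f_start = f_start, f_stop = f_stop, n_points = n_points,
         freq = freq, step = (f_stop - f_start) / (n_points - 1)),
    class = "freq_grid"
  )
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("<freq_grid> %g-%g GHz, %d points (%.4g MHz spacing)\n",
              x$f_start, x$f_stop, x$n_points, x$step * 1000))
  invisible(x)
}

# Snap a frequency to the nearest grid point (first on ties).
grid_snap <- function(grid, f) {
  grid$freq[argmin_first(abs(grid$freq - f))]
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_points == b$n_points &&
    abs(a$f_start - b$f_start) < tol && abs(a$f_stop - b$f_stop) < tol
}
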