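# Internal helpers shared across modules.

# Round-half-up on sample counts (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Index of the minimum with ties broken toward the first (lowest) index.
argmin_first <- function(x) which.min(x)

argmax_first <- function(x) which.max(x)

# Unwrap a phase series along its ordering axis (jumps > pi folded back).
unwrap_phase <- function(phi) {
  if (length(phi) < 2) return(phi)
  d <- diff(phi)
  correction <- cumsum(-2 * pi * round(d / (2 * pi)))
  c(phi[1], phi[-1] + correction)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "icp_invalid_config")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name),
          class = "icp_invalid_config")
  }
  invisible(x)
}
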