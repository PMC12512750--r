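# Dataset-variant creation and trial-disjoint splitting.

#' Four overlapping dataset variants of a processed trial
#'
#' Slices one processed trial into the four variants that stabilize the
#' downstream analysis: the full record, its first 80 %, its last 80 % and
#' its middle 80 % (from 10 % to 90 %). Fractions are applied to the sample
#' count with round-half-up; ranges are 1-based inclusive over the
#' processed trial's sweeps.
#'
#' @param processed An `icp_processed` (or anything with a `pressure`
#'   vector) with at least 10 sweeps.
#' @return Tibble with one row per variant: `variant` (`"Ds1"`..`"Ds4"`),
#'   `k`, `a`, `b` (inclusive sweep range) and `n_sweeps`.
#' @examples
#' create_variants(list(pressure = numeric(100)))
#' @export
create_variants <- function(processed) {
  n <- length(processed$pressure)
  if (n < 10) {
    abort(sprintf("Need at least 10 sweeps to form the variants (got %d).", n),
          class = "icp_invalid_config")
  }
  n80 <- round_half_up(0.8 * n)
  n10 <- round_half_up(0.1 * n)
  out <- tibble::tibble(
    variant = c("Ds1", "Ds2", "Ds3", "Ds4"),
    k = 1:4,
    a = c(1L, 1L, as.integer(n - n80 + 1), as.integer(n10 + 1)),
    b = c(as.integer(n), as.integer(n80), as.integer(n),
          as.integer(n10 + n80))
  )
  out$n_sweeps <- out$b - out$a + 1L
  out
}

#' Random trial-disjoint train/test/validation split
#'
#' Partitions whole trials — never samples within a trial — into training
#' (80 %), testing (10 %) and validation (10 %) roles so that evaluation is
#' always on sweeps from independent trials. Counts use largest-remainder
#' rounding with every role guaranteed non-empty for three or more trials.
#'
#' @param trial_ids Vector of unique trial identifiers (length >= 3).
#' @param seed Integer seed; the same seed yields the same assignment.
#' @param proportions Role proportions, summing to 1.
#' @return Tibble of class `split_assignment` with columns `trial_id`,
#'   `role` (factor train/test/validation) and a `seed` attribute.
#' @export
split_trials <- function(trial_ids, seed = 1L,
                         proportions = c(train = 0.8, test = 0.1,
                                         validation = 0.1)) {
  trial_ids <- unique(trial_ids)
  n <- length(trial_ids)
  if (n < 3) {
    abort("Need at least 3 trials for a three-way split.",
          class = "icp_invalid_config")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must sum to 1.", class = "icp_invalid_config")
  }
  quota <- proportions * n
  counts <- pmax(floor(quota), 1)
  # Largest-remainder completion, then trim any overshoot from the largest
  # role, keeping every role at >= 1.
  rem <- quota - floor(quota)
  while (sum(counts) < n) {
    i <- order(-rem, seq_along(rem))[1]
    counts[i] <- counts[i] + 1
    rem[i] <- -Inf
  }
  while (sum(counts) > n) {
    i <- which.max(ifelse(counts > 1, counts, -Inf))
    counts[i] <- counts[i] - 1
  }
  roles <- rep(names(proportions), times = counts)
  perm <- with_fixed_seed(as.integer(seed), sample.int(n))
  out <- tibble::tibble(
    trial_id = trial_ids[perm],
    role = factor(roles, levels = names(proportions))
  )
  out <- out[order(match(out$trial_id, trial_ids)), ]
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("split_assignment", class(out))
  out
}

#' Trial ids holding a given role
#'
#' @param split A `split_assignment`.
#' @param role One of `"train"`, `"test"`, `"validation"`.
#' @return Vector of trial ids.
#' @export
split_role <- function(split, role) {
  split$trial_id[split$role == role]
}
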