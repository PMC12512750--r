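# Cleaning, band selection and time limiting.

test_that("zeta1 maps constant strings to zeros and flags lone spikes", {
  z <- zeta1_clean(c(5, 5, 5, 5))
  expect_equal(z$normalized, rep(0, 4))
  z <- zeta1_clean(c(0, 0, 0, 100, 0, 0, 0))
  expect_equal(which(z$outliers), 4)
  expect_equal(z$cleaned[4], 0)
  expect_error(zeta1_clean(numeric(0)), class = "icp_empty_input")
})

test_that("zeta1 normalization yields ~standard-normal output at n = 1e4", {
  set.seed(123)
  z <- zeta1_clean(rnorm(1e4))
  expect_lt(abs(mean(z$normalized)), 0.05)
  expect_lt(abs(sd(z$normalized) - 1), 0.05)
})

test_that("hampel filter agrees with a brute-force median/MAD scan", {
  oracle <- function(x, window = 11, k = 3) {
    h <- floor(window / 2)
    out <- logical(length(x))
    for (i in seq_along(x)) {
      j <- max(1, i - h):min(length(x), i + h)
      med <- median(x[j])
      out[i] <- abs(x[i] - med) > k * 1.4826 * median(abs(x[j] - med))
    }
    out
  }
  set.seed(42)
  for (rep in 1:10) {
    x <- rnorm(60)
    spikes <- sample(60, 3)
    x[spikes] <- x[spikes] + sample(c(-30, 30), 3, replace = TRUE)
    expect_identical(hampel_filter(x)$outliers, oracle(x))
  }
})

test_that("locate_minima matches an exhaustive scan and breaks ties low", {
  set.seed(31)
  freq <- seq(2, 6, length.out = 50)
  frames <- matrix(rnorm(10 * 50), 10, 50)
  got <- locate_minima(frames, freq)
  for (k in 1:10) {
    expect_equal(got$loc_GHz[k], freq[which.min(frames[k, ])])
    expect_equal(got$val_db[k], min(frames[k, ]))
  }
  tied <- matrix(5, 1, 50)
  tied[1, c(10, 20)] <- -1
  expect_equal(locate_minima(tied, freq)$loc_GHz, freq[10])
})

test_that("minimum location is invariant under monotone transforms", {
  set.seed(8)
  freq <- seq(2, 6, length.out = 40)
  frames <- matrix(rnorm(5 * 40), 5, 40)
  base <- locate_minima(frames, freq)$loc_GHz
  expect_equal(locate_minima(exp(frames / 3), freq)$loc_GHz, base)
  expect_equal(locate_minima(frames^3, freq)$loc_GHz, base)
})

test_that("optimal_frequency picks the only temporally active bin", {
  freq <- seq(2, 6, length.out = 20)
  frames <- matrix(1, 6, 20)
  frames[, 13] <- 1 + seq_len(6)
  expect_equal(optimal_frequency(frames, freq), freq[13])
})

test_that("optimal_frequency equals a brute-force per-bin range scan", {
  set.seed(77)
  for (i in 1:100) {
    n_f <- sample(5:40, 1)
    n_t <- sample(3:15, 1)
    freq <- seq(2, 6, length.out = n_f)
    frames <- matrix(rnorm(n_t * n_f), n_t, n_f)
    rng <- sapply(seq_len(n_f), function(j) max(frames[, j]) - min(frames[, j]))
    expect_equal(optimal_frequency(frames, freq), freq[which.max(rng)])
  }
})

test_that("optimal_frequency recovers the planted coupling centre", {
  cfg <- quick_config(trace_noise_db = 0, pulse_amp = 0,
                      coupling = coupling_model(alpha_mag_db = -0.05,
                                                beta_freq_mhz = 0,
                                                gamma_phase_rad = 0))
  tr <- simulate_trial(cfg)
  f0 <- sensor_profile("A", cfg$grid)$resonance_f0
  expect_equal(optimal_frequency(tr$sxx_mag, cfg$grid$freq), f0)
})

test_that("temporally constant input is a degenerate case", {
  frames <- matrix(3, 5, 10)
  expect_error(optimal_frequency(frames, seq(2, 6, length.out = 10)),
               class = "icp_degenerate_input")
})

test_that("optimal band is f_opt +/- 50 MHz intersected with the grid", {
  fine <- freq_grid(2, 6, 4001)   # 1 MHz spacing holds 3.565 exactly
  band <- optimal_band(3.565, fine)
  expect_equal(band$f_lo, 3.515)
  expect_equal(band$f_hi, 3.615)
  expect_true(3.565 >= band$f_lo && 3.565 <= band$f_hi)

  std <- freq_grid()              # 2 MHz spacing: 51 bins in a 100 MHz band
  band2 <- optimal_band(std$freq[800], std)
  expect_length(band2$bins, 51)

  clipped <- optimal_band(std$f_start, std)
  expect_equal(clipped$f_lo, std$f_start)
  expect_equal(clipped$f_hi, std$f_start + 0.05)
})

test_that("time limiting removes the pressure-quiet lead", {
  # Flat for 10 sweeps, then a 0.15 mmHg/s ramp sampled at 1 Hz: the
  # centred slope first exceeds 0.1 mmHg/s at sweep 11.
  p <- c(rep(0, 10), 0.15 * (1:20))
  tr <- flat_trial(p)
  band <- optimal_band(tr$grid$freq[6], tr$grid, f_th_mhz = 500)
  lim <- zeta2_limit(tr, band)
  expect_equal(lim$retained[1], 11)
  expect_equal(nrow(lim$baseline$sxx_mag), 10)

  active <- flat_trial(0.15 * (1:20))
  lim2 <- zeta2_limit(active, band)
  expect_equal(lim2$retained[1], 1)

  expect_error(zeta2_limit(flat_trial(rep(5, 20)), band),
               class = "icp_degenerate_input")
})

test_that("time limiting stops where pressure first attains its maximum", {
  p <- c(rep(0, 5), seq(0.5, 10, by = 0.5), rep(10, 8))
  tr <- flat_trial(p)
  band <- optimal_band(tr$grid$freq[6], tr$grid, f_th_mhz = 500)
  lim <- zeta2_limit(tr, band)
  expect_equal(max(lim$retained), which(p == 10)[1])
})

test_that("preprocessing then features commutes with band restriction", {
  pr <- quick_processed()
  # Features computed on the band-limited matrices equal features computed
  # on full-band matrices restricted to the band bins.
  full <- quick_trial()
  cleaned_full <- icpsweep:::zeta1_clean_matrix(full$sxx_mag)$cleaned
  sub <- cleaned_full[pr$retained, pr$band$bins, drop = FALSE]
  expect_equal(apply(pr$sxx_mag, 1, min), apply(sub, 1, min))
  expect_equal(apply(pr$sxx_mag, 1, band_auc, freq = pr$freq),
               apply(sub, 1, band_auc, freq = pr$freq))
})

test_that("averaging five identical trials gives zero SEM", {
  pr <- quick_processed()
  avg <- average_trials(rep(list(pr), 5))
  expect_equal(max(abs(avg$sem$sxx_mag)), 0)
  expect_equal(avg$mean$sxx_mag, pr$sxx_mag)
  expect_equal(avg$n, 5)
})

test_that("SEM follows sd/sqrt(n) cell-wise", {
  pr <- quick_processed()
  trials <- lapply(1:5, function(i) {
    p <- pr
    p$sxx_mag[1, 1] <- i   # cell values 1..5
    p
  })
  avg <- average_trials(trials)
  expect_equal(avg$mean$sxx_mag[1, 1], 3)
  expect_equal(avg$sem$sxx_mag[1, 1], sqrt(2.5) / sqrt(5))
})

test_that("averaging warns on a non-standard trial count and mixed cells", {
  pr <- quick_processed()
  expect_warning(avg <- average_trials(rep(list(pr), 4)), "4")
  expect_equal(avg$n, 4)
  other <- pr
  other$placement <- "5 mm"
  expect_error(average_trials(list(pr, other)), class = "icp_invalid_config")
})
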