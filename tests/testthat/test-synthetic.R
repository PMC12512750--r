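# Phantom simulator: trajectories, sensor profiles, coupled sweeps.

test_that("pressure trajectory ramps to p_max with a flat lead segment", {
  traj <- pressure_trajectory(duration_s = 120, lead_s = 10,
                              ref_rate_hz = 100, pulse_amp = 0)
  expect_equal(max(traj$p_mmHg), 60)
  expect_equal(traj$p_mmHg[length(traj$p_mmHg)], 60)
  expect_true(all(traj$p_mmHg[traj$time_s < 10] == 0))
  expect_true(all(diff(traj$p_mmHg) >= 0))  # no pulsation: nondecreasing
})

test_that("pulsatile component is zero-mean: beat means follow the ramp", {
  rate <- 2000
  traj <- pressure_trajectory(duration_s = 30, lead_s = 5, p_max = 60,
                              pulse_rate = 60, pulse_amp = 2,
                              ref_rate_hz = rate)
  # Whole beats start at the pump onset (lead_s); beat length 1 s at 60 bpm.
  ramp <- attr(traj, "ramp")
  for (beat_start in c(5, 10, 17)) {
    sel <- traj$time_s >= beat_start - 1e-12 &
      traj$time_s <= beat_start + 1 + 1e-12
    beat_mean <- pracma::trapz(traj$time_s[sel], traj$p_mmHg[sel])
    centre_val <- ramp[which.min(abs(traj$time_s - (beat_start + 0.5)))]
    expect_equal(beat_mean, centre_val, tolerance = 1e-6)
  }
})

test_that("trajectory rejects invalid configurations", {
  expect_error(pressure_trajectory(duration_s = -1), class = "icp_invalid_config")
  expect_error(pressure_trajectory(duration_s = 10, lead_s = 10),
               class = "icp_invalid_config")
  expect_error(pressure_trajectory(pulse_rate = 0), class = "icp_invalid_config")
})

test_that("sensor profiles reproduce the published resonance minima", {
  # 1 MHz spacing represents the printed dip frequencies exactly.
  fine <- freq_grid(2, 6, 4001)
  a <- sensor_profile("A", fine)
  expect_equal(fine$freq[which.min(a$baseline_sxx)], 3.565)
  expect_equal(min(a$baseline_sxx), -35.3)
  b <- sensor_profile("B", fine)
  expect_equal(fine$freq[which.min(b$baseline_sxy)], 3.604)
  expect_equal(min(b$baseline_sxy), -65.87)
  expect_equal(fine$freq[which.min(b$baseline_sxx)], 3.658)
  d <- sensor_profile("D", fine)
  expect_equal(min(d$baseline_sxx), -22.83)
  expect_equal(fine$freq[which.min(d$baseline_sxx)], 3.21)
})

test_that("profile minima sit on the supplied grid (snapped deterministically)", {
  std <- freq_grid()  # 2 MHz spacing: 3.565 GHz is not representable
  a <- sensor_profile("A", std)
  i <- which.min(a$baseline_sxx)
  expect_equal(a$resonance_f0, std$freq[i])
  expect_lte(abs(std$freq[i] - 3.565), std$step)
  expect_equal(min(a$baseline_sxx), -35.3)
})

test_that("unknown sensor ids are rejected", {
  expect_error(sensor_profile("Z"), class = "icp_unknown_sensor")
  expect_error(sensor_profile(1), class = "icp_unknown_sensor")
})

test_that("zero coupling and zero noise reproduce the baseline exactly", {
  cfg <- quick_config(coupling = coupling_model(0, 0, 0),
                      trace_noise_db = 0)
  tr <- simulate_trial(cfg)
  prof <- sensor_profile("A", cfg$grid)
  for (k in c(1, nrow(tr$sxx_mag))) {
    expect_equal(tr$sxx_mag[k, ], prof$baseline_sxx)
    expect_equal(tr$sxy_mag[k, ], prof$baseline_sxy)
    expect_equal(tr$sxx_phase[k, ], prof$baseline_phase_sxx)
  }
})

test_that("frequency coupling shifts the resonance by beta * p on the grid", {
  # 2 MHz grid; 0.1 MHz/mmHg at 60 mmHg = 6 MHz = 3 bins.
  cfg <- sim_config(grid = freq_grid(2, 6, 2001), duration_s = 20,
                    lead_s = 2, ref_rate_hz = 100, pulse_amp = 0,
                    trace_noise_db = 0,
                    coupling = coupling_model(alpha_mag_db = 0,
                                              beta_freq_mhz = 0.1,
                                              gamma_phase_rad = 0))
  tr <- simulate_trial(cfg)
  tr <- align_reference(tr)
  last <- nrow(tr$sxx_mag)
  f0 <- sensor_profile("A", cfg$grid)$resonance_f0
  expected_shift <- 0.1 / 1000 * tr$pressure[last]
  expected_loc <- cfg$grid$freq[which.min(abs(
    cfg$grid$freq - (f0 + expected_shift)))]
  got <- cfg$grid$freq[which.min(tr$sxx_mag[last, ])]
  expect_equal(got, expected_loc)
})

test_that("identical configurations give identical trials", {
  t1 <- simulate_trial(quick_config(seed = 99))
  t2 <- simulate_trial(quick_config(seed = 99))
  expect_identical(t1, t2)
  t3 <- simulate_trial(quick_config(seed = 100))
  expect_false(identical(t1$sxx_mag, t3$sxx_mag))
})

test_that("sweep count equals floor(duration x sweep rate)", {
  for (dur in c(5, 7.4, 15)) {
    cfg <- quick_config(duration_s = dur)
    expect_equal(nrow(simulate_trial(cfg)$sxx_mag), floor(dur * 3))
  }
})

test_that("amplitude coupling is linear: doubling alpha doubles the offset", {
  base <- simulate_trial(quick_config(coupling = coupling_model(0, 0, 0),
                                      trace_noise_db = 0))
  c1 <- simulate_trial(quick_config(
    coupling = coupling_model(alpha_mag_db = -0.05, beta_freq_mhz = 0,
                              gamma_phase_rad = 0), trace_noise_db = 0))
  c2 <- simulate_trial(quick_config(
    coupling = coupling_model(alpha_mag_db = -0.1, beta_freq_mhz = 0,
                              gamma_phase_rad = 0), trace_noise_db = 0))
  d1 <- c1$sxx_mag - base$sxx_mag
  d2 <- c2$sxx_mag - base$sxx_mag
  expect_equal(d2, 2 * d1)
})

test_that("trace noise matches the configured RMS under constant pressure", {
  cfg <- sim_config(grid = freq_grid(2, 6, 21), duration_s = 400,
                    lead_s = 399, ref_rate_hz = 10, pulse_amp = 0,
                    coupling = coupling_model(0, 0, 0),
                    trace_noise_db = 5e-3, seed = 4L)
  tr <- simulate_trial(cfg)   # 1200 sweeps, all at zero pressure until lead
  sds <- apply(tr$sxx_mag[1:1100, ], 2, sd)
  expect_true(all(abs(sds - 5e-3) / 5e-3 < 0.1))
})

test_that("coupling that pushes the resonance off-grid is rejected", {
  cfg <- quick_config(coupling = coupling_model(beta_freq_mhz = 60))
  expect_error(simulate_trial(cfg), class = "icp_invalid_config")
})

test_that("campaigns enumerate sensors, placements and repeats", {
  trials <- simulate_campaign(sensors = "A", placements = c("5 mm", "10 mm"),
                              trials_per_placement = 2,
                              config = quick_config(duration_s = 5))
  expect_length(trials, 4)
  expect_setequal(vapply(trials, `[[`, character(1), "placement"),
                  c("5 mm", "10 mm"))
  expect_equal(sort(vapply(trials, `[[`, integer(1), "trial_index")), 1:4)
})
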