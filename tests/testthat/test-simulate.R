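# Synthetic cohort generator: cardiac carrier, hemodynamic response,
# session and cohort structure, ground-truth faithfulness.

test_that("cardiac carrier is periodic, asymmetric, and mean-preserving", {
  fs <- 250  # fine grid for the integral checks
  t <- seq(0, 60, by = 1 / fs)
  v <- cardiac_waveform(t, heart_rate_bpm = 60, baseline_cm_s = 50,
                        pulsatility_fraction = 0.5)

  # one-cycle mean equals the baseline
  expect_equal(mean(v[t >= 1 & t < 2]), 50, tolerance = 0.5 / 50)

  # 60 s at 60 bpm: 60 interior local maxima
  n <- length(v)
  is_max <- v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]
  expect_equal(sum(is_max), 60)

  # asymmetric within-cycle shape: systolic rise much faster than decay
  cyc <- v[t >= 1 & t < 2]
  expect_lt(which.max(cyc) / length(cyc), 0.5)

  # vanishing modulation gives the constant baseline
  expect_equal(cardiac_waveform(t, 60, 50, 1e-12), rep(50, length(t)),
               tolerance = 1e-9)

  # strictly positive across the default parameter ranges
  for (hr in c(55, 70, 85)) {
    for (base in c(45, 55, 65)) {
      expect_true(all(cardiac_waveform(t, hr, base, 0.5) > 0))
    }
  }

  expect_error(cardiac_waveform(t, -10, 50, 0.5), "heart_rate")
  expect_error(cardiac_waveform(t, 60, 0, 0.5), "baseline")
})

test_that("hemodynamic response peaks at the requested delay and amplitude", {
  t <- seq(-5, 25, by = 0.04)  # 25 Hz grid
  r <- hemodynamic_response(t, amplitude_pct = 5, peak_delay_s = 6,
                            width_s = 4)

  expect_true(all(r[t < 0] == 0))
  expect_equal(hemodynamic_response(6, 5, 6, 4), 5)
  expect_equal(t[which.max(r)], 6, tolerance = 0.04 + 1e-12)
  expect_identical(hemodynamic_response(t, 0, 6, 4), rep(0, length(t)))

  # unimodal up to the plateau: nondecreasing to the peak, then nonincreasing
  expect_true(all(diff(r[t >= 0 & t <= 6]) >= -1e-12))
  expect_true(all(diff(r[t >= 6]) <= 1e-12))

  # plateau persists at the configured fraction
  expect_equal(r[t == 25], 5 * 0.6, tolerance = 1e-3)

  expect_error(hemodynamic_response(t, 5, 6, -1), "width")
})

test_that("simulated sessions carry the block design", {
  sess <- quiet_session(seed = 5)
  ev <- sess$events

  expect_s3_class(sess, "ftcd_session")
  expect_equal(sum(ev$kind == "target"), 20)
  expect_identical(ev$kind[1], "control")
  expect_identical(ev$kind[nrow(ev)], "control")
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  expect_true(!is.unsorted(ev$onset_s, strictly = TRUE))

  # total duration bounded by the interval ranges
  total <- length(sess$left_velocity) / sess$sample_rate_hz
  expect_gte(total, 20 * (25 + 15) + 15)
  expect_lte(total, 20 * (35 + 25) + 25 + 1)

  expect_true(all(sess$left_velocity > 0))
  expect_true(all(sess$right_velocity > 0))
  expect_length(sess$right_velocity, length(sess$left_velocity))
})

test_that("target intervals carry the response, controls do not", {
  sess <- quiet_session(amp_left = 8, amp_right = 8, seed = 9)
  beats <- detect_cardiac_cycles(sess)
  smooth <- integrate_cardiac(sess, beats)

  ev <- sess$events
  targ1 <- ev$onset_s[ev$kind == "target"][1]
  # late in the first target interval the plateau should be visible
  sel_t <- smooth$time_s >= targ1 + 8 & smooth$time_s <= targ1 + 15
  lift <- mean(smooth$left_velocity[sel_t]) / sess$baseline_cm_s - 1
  expect_gt(lift * 100, 3)
  # pre-onset control is at baseline
  sel_c <- smooth$time_s >= targ1 - 5 & smooth$time_s < targ1 - 1
  drift <- mean(smooth$left_velocity[sel_c]) / sess$baseline_cm_s - 1
  expect_lt(abs(drift * 100), 1)
})

test_that("cohorts are deterministic given the seed", {
  cfg <- ftcd_config(n_subjects = 2, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sessions, b$sessions)

  c2 <- simulate_cohort(ftcd_config(n_subjects = 2, seed = 124))
  expect_false(identical(a$sessions[[1]]$left_velocity,
                         c2$sessions[[1]]$left_velocity))
})

test_that("ground-truth cross-task correlation matches the trait model", {
  # perfect sharing: identical latent draw, correlation exactly 1
  co1 <- simulate_cohort(ftcd_config(n_subjects = 8, trait_sd_pct = 2,
                                     trait_cross_task_correlation = 1,
                                     n_epochs = 1, seed = 21))
  tr <- co1$truth
  dA <- tr$true_delta_v_pct[tr$task_label == "language"]
  dB <- tr$true_delta_v_pct[tr$task_label == "knapping"]
  expect_equal(stats::cor(dA, dB), 1, tolerance = 1e-12)

  # rho = 0.9 converges at cohort scale (sampling error only)
  co2 <- simulate_cohort(ftcd_config(n_subjects = 500, trait_sd_pct = 2,
                                     trait_cross_task_correlation = 0.9,
                                     n_epochs = 1, seed = 22))
  tr2 <- co2$truth
  r <- stats::cor(tr2$true_delta_v_pct[tr2$task_label == "language"],
                  tr2$true_delta_v_pct[tr2$task_label == "knapping"])
  expect_equal(r, 0.9, tolerance = 0.05)

  # negative correlation is honored too
  co3 <- simulate_cohort(ftcd_config(n_subjects = 500, trait_sd_pct = 2,
                                     trait_cross_task_correlation = -0.6,
                                     n_epochs = 1, seed = 23))
  tr3 <- co3$truth
  r3 <- stats::cor(tr3$true_delta_v_pct[tr3$task_label == "language"],
                   tr3$true_delta_v_pct[tr3$task_label == "knapping"])
  expect_equal(r3, -0.6, tolerance = 0.07)

  # injected amplitudes decompose as effect +/- trait/2
  expect_equal(tr2$true_delta_v_pct,
               tr2$amp_left_pct - tr2$amp_right_pct, tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(ftcd_config(pulsatility_fraction = 1.2), "pulsatility")
  expect_error(ftcd_config(trait_cross_task_correlation = 1.5), "correlation")
  expect_error(ftcd_config(artifact_amplitude_pct = 20), "exceed 30")
  expect_error(ftcd_config(target_duration_range_s = c(35, 25)), "ranges")
  expect_error(ftcd_config(noise_sd_pct = -1), "noise_sd_pct")
})

test_that("n_epochs = 1 sessions simulate cheaply for unit fixtures", {
  sess <- quiet_session(n_epochs = 1, seed = 2)
  expect_equal(sum(sess$events$kind == "target"), 1)
  expect_lt(length(sess$left_velocity) / sess$sample_rate_hz, 90)
})
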