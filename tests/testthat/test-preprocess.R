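# Preprocessing chain: cycle detection, cardiac integration, epoch
# segmentation and normalization, artifact rejection, QC, filtering.

test_that("cardiac cycles are detected at the simulated rate", {
  sess <- carrier_session(duration_s = 120, heart_rate = 60)
  beats <- detect_cardiac_cycles(sess)

  expect_s3_class(beats, "ftcd_beats")
  n_cyc <- nrow(beats$cycles)
  expect_gte(n_cyc, 117)
  expect_lte(n_cyc, 120)

  # durations near 1 s, within physiological bounds
  expect_true(all(beats$cycles$duration_s >= 0.3))
  expect_true(all(beats$cycles$duration_s <= 2))
  expect_equal(stats::median(beats$cycles$duration_s), 1, tolerance = 0.05)

  # boundaries strictly increasing
  expect_true(!is.unsorted(beats$cycle_boundaries_s, strictly = TRUE))

  # cycle means recover the baseline on both channels
  expect_equal(beats$cycles$mean_left, rep(50, n_cyc), tolerance = 0.5 / 50)
  expect_equal(beats$cycles$mean_right, rep(50, n_cyc), tolerance = 0.5 / 50)
})

test_that("constant or absent pulsatility raises a no-cardiac-signal error", {
  sess <- carrier_session(duration_s = 60)
  sess$left_velocity <- rep(50, length(sess$left_velocity))
  sess$right_velocity <- sess$left_velocity
  expect_error(detect_cardiac_cycles(sess), "no cardiac signal")

  short <- carrier_session(duration_s = 5)
  expect_error(detect_cardiac_cycles(short), "at least 10 s")
})

test_that("cardiac integration removes pulsatility, keeps slow structure", {
  sess <- carrier_session(duration_s = 120)
  beats <- detect_cardiac_cycles(sess)
  smooth <- integrate_cardiac(sess, beats)

  expect_length(smooth$left_velocity, length(sess$left_velocity))
  # pure carrier flattens to the baseline
  interior <- smooth$time_s > 2 & smooth$time_s < 118
  expect_true(all(abs(smooth$left_velocity[interior] - 50) < 0.5))

  # a ramp in the envelope survives integration with at most a cycle's lag
  ramp <- carrier_session(duration_s = 120)
  slope <- 0.1  # cm/s per s
  mod <- 1 + slope * ramp$time_s / 50
  ramp$left_velocity <- ramp$left_velocity * mod
  ramp$right_velocity <- ramp$right_velocity * mod
  sm <- integrate_cardiac(ramp, detect_cardiac_cycles(ramp))
  sel <- sm$time_s > 5 & sm$time_s < 115
  expected <- 50 + slope * sm$time_s[sel]
  expect_true(max(abs(sm$left_velocity[sel] - expected)) < slope * 1.2)
})

test_that("epoch segmentation normalizes to the pre-onset baseline", {
  sess <- quiet_session(seed = 31)
  smooth <- integrate_cardiac(sess, detect_cardiac_cycles(sess))
  ep <- segment_epochs(smooth)

  expect_equal(ep$n_total, 20)
  expect_equal(ep$time_axis_s[1], -5)
  expect_equal(ep$time_axis_s[length(ep$time_axis_s)], 25)

  # reconstructing the raw trace from dv and V_b: its baseline-window mean
  # is V_b exactly, so the dv baseline mean is 0 to floating tolerance
  bl <- ep$time_axis_s >= -5 & ep$time_axis_s < 0
  for (j in seq_len(ep$n_total)) {
    expect_equal(mean(ep$dv_left_pct[bl, j]), 0, tolerance = 1e-9)
    expect_equal(mean(ep$dv_right_pct[bl, j]), 0, tolerance = 1e-9)
    raw <- ep$baseline_left_cm_s[j] * (1 + ep$dv_left_pct[, j] / 100)
    expect_equal(mean(raw[bl]), ep$baseline_left_cm_s[j], tolerance = 1e-9)
  }
})

test_that("percent change follows its definition", {
  # constant channel: dv identically zero; a 55 cm/s excursion over a
  # 50 cm/s baseline reads +10%
  sess <- carrier_session(duration_s = 80)
  sess$left_velocity <- rep(50, length(sess$time_s))
  sess$right_velocity <- rep(50, length(sess$time_s))
  lift <- sess$time_s >= 25 & sess$time_s < 35
  sess$left_velocity[lift] <- 55
  sess$events <- data.frame(onset_s = c(0, 20, 55),
                            kind = c("control", "target", "control"),
                            stringsAsFactors = FALSE)
  ep <- segment_epochs(sess)  # no integration: tests the normalization only
  expect_equal(ep$n_total, 1)
  in_lift <- ep$time_axis_s >= 5.5 & ep$time_axis_s < 14.5
  expect_true(all(abs(ep$dv_left_pct[in_lift, 1] - 10) < 1e-9))
  expect_true(all(abs(ep$dv_right_pct[, 1]) < 1e-9))
})

test_that("epochs without a full window are dropped with a warning", {
  sess <- carrier_session(duration_s = 60)
  sess$events <- data.frame(onset_s = c(0, 2, 40),
                            kind = c("control", "target", "control"),
                            stringsAsFactors = FALSE)
  expect_warning(ep <- segment_epochs(sess), "dropped 1 target")
  expect_equal(ep$n_total, 0)
})

test_that("scaling both channels leaves percent traces unchanged", {
  sess <- quiet_session(seed = 33, n_epochs = 2)
  for (k in c(0.5, 3)) {
    scaled <- sess
    scaled$left_velocity <- k * sess$left_velocity
    scaled$right_velocity <- k * sess$right_velocity
    ep0 <- segment_epochs(integrate_cardiac(sess,
                                            detect_cardiac_cycles(sess)))
    ep1 <- segment_epochs(integrate_cardiac(scaled,
                                            detect_cardiac_cycles(scaled)))
    expect_equal(ep1$dv_left_pct, ep0$dv_left_pct, tolerance = 1e-9)
    expect_equal(ep1$dv_right_pct, ep0$dv_right_pct, tolerance = 1e-9)
  }
})

test_that("artifact rejection applies a strict 30% threshold", {
  base <- matrix(0, 751, 4)
  dv <- base
  dv[100, 2] <- 31    # above threshold: rejected
  dv[200, 3] <- 30    # exactly at threshold: kept
  dv[300, 4] <- -31   # negative excursions count too
  ep <- manual_epochs(dv)
  out <- reject_artifacts(ep)

  expect_identical(out$good_flag, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$n_good, 2)

  # excursion on the right channel alone also rejects
  dvr <- base
  dvr[50, 1] <- 40
  out2 <- reject_artifacts(manual_epochs(base, dvr))
  expect_identical(out2$good_flag, c(FALSE, TRUE, TRUE, TRUE))

  # idempotence
  expect_identical(reject_artifacts(out), out)
})

test_that("injected artifacts are caught end to end", {
  sess <- quiet_session(seed = 35)
  onsets <- sess$events$onset_s[sess$events$kind == "target"]
  for (j in c(2, 7, 11, 19)) {
    sess <- inject_artifact(sess, onsets[j] + 6, 1.5, 60,
                            channel = if (j %% 2) "left" else "right")
  }
  ep <- reject_artifacts(segment_epochs(
    integrate_cardiac(sess, detect_cardiac_cycles(sess))))
  expect_equal(ep$n_total, 20)
  expect_equal(ep$n_good, 16)
  expect_identical(which(!ep$good_flag), c(2L, 7L, 11L, 19L))
})

test_that("subject QC retains exactly at the 80% boundary", {
  dv_ok <- matrix(0, 751, 20)
  make_set <- function(n_bad) {
    dv <- dv_ok
    if (n_bad > 0) dv[1, seq_len(n_bad)] <- 50
    reject_artifacts(manual_epochs(dv))
  }
  qc1 <- qc_subject(list(language = make_set(4), knapping = make_set(0)))
  expect_true(qc1$keep)   # 16/20 = 0.80 is not "less than 80%"
  expect_equal(qc1$report$fraction, c(0.8, 1.0))
  expect_equal(qc1$report$n_good, c(16, 20))

  qc2 <- qc_subject(list(language = make_set(5), knapping = make_set(0)))
  expect_false(qc2$keep)  # 15/20 < 0.80 in one condition suffices

  # empty epoch set excludes
  empty <- manual_epochs(matrix(numeric(0), 751, 0))
  expect_false(qc_subject(list(a = empty))$keep)
})

test_that("the zero-phase Butterworth filter honors its contract", {
  fs <- 25
  # unit DC gain on a constant
  x <- rep(3.5, 751)
  expect_equal(zero_phase_butter(x, fs), x, tolerance = 1e-6)

  # 1 Hz sinusoid attenuated to amplitude 0.50 after two passes
  t <- seq(0, 60, by = 1 / fs)
  y <- zero_phase_butter(sin(2 * pi * t), fs, cutoff_hz = 1, order = 2)
  interior <- t > 10 & t < 50
  amp <- (max(y[interior]) - min(y[interior])) / 2
  expect_equal(amp, 0.5, tolerance = 0.02)

  # well below the cutoff the signal passes essentially unchanged
  slow <- sin(2 * pi * 0.05 * t)
  expect_equal(zero_phase_butter(slow, fs)[interior], slow[interior],
               tolerance = 0.01)

  # time-reversal symmetry of the zero-phase pass
  set.seed(44)
  z <- cumsum(rnorm(600)) / 10
  expect_equal(rev(zero_phase_butter(rev(z), fs)),
               zero_phase_butter(z, fs), tolerance = 1e-9)

  # symmetric input gives symmetric output
  s <- exp(-((seq(-10, 10, by = 1 / fs)) / 2)^2)
  fy <- zero_phase_butter(s, fs)
  expect_equal(fy, rev(fy), tolerance = 1e-9)

  expect_error(zero_phase_butter(x, fs, cutoff_hz = 20), "Nyquist")
})

test_that("averaging uses only good epochs and fails with none", {
  dv <- matrix(0, 751, 3)
  dv[, 1] <- 2
  dv[, 2] <- 4
  dv[1, 3] <- 99  # to be rejected
  ep <- reject_artifacts(manual_epochs(dv))
  resp <- average_and_filter(ep)
  expect_equal(resp$n_good_epochs, 2)
  expect_equal(mean(resp$mean_dv_left_pct), 3, tolerance = 1e-6)

  ep$good_flag[] <- FALSE
  expect_error(average_and_filter(ep), "no usable epochs")
})

test_that("noise-free pipeline recovers the injected response shape", {
  amp_l <- 6
  amp_r <- 2
  sess <- quiet_session(amp_left = amp_l, amp_right = amp_r, seed = 37)
  pp <- preprocess_session(sess)
  resp <- pp$response

  t <- resp$time_axis_s
  cfg <- quiet_config()
  expected_l <- amp_l * hemodynamic_response(t, 1, cfg$hrf_peak_delay_s,
                                             cfg$hrf_width_s,
                                             cfg$hrf_plateau_frac)
  expected_r <- (amp_r / amp_l) * expected_l
  sel <- t >= -4 & t <= 20  # clear of epoch-edge filter transients
  expect_lt(max(abs(resp$mean_dv_left_pct[sel] - expected_l[sel])), 2)
  expect_lt(max(abs(resp$mean_dv_right_pct[sel] - expected_r[sel])), 2)
})

test_that("tiny sessions match the brute-force reference chain", {
  for (seed in c(51, 52)) {
    sess <- quiet_session(seed = seed, n_epochs = 2, amp_left = 5,
                          amp_right = 1)
    pp <- preprocess_session(sess)
    oracle <- oracle_preprocess(sess)

    # pre-filter stages agree essentially exactly
    expect_equal(ncol(pp$epochs$dv_left_pct), length(oracle$dv_left))
    for (j in seq_along(oracle$dv_left)) {
      expect_equal(pp$epochs$dv_left_pct[, j], oracle$dv_left[[j]],
                   tolerance = 1e-12)
      expect_equal(pp$epochs$dv_right_pct[, j], oracle$dv_right[[j]],
                   tolerance = 1e-12)
    }
    expect_identical(pp$epochs$good_flag, oracle$good)

    # filtered averages agree to 1e-9
    expect_equal(pp$response$mean_dv_left_pct, oracle$mean_left_filt,
                 tolerance = 1e-9)
    expect_equal(pp$response$mean_dv_right_pct, oracle$mean_right_filt,
                 tolerance = 1e-9)
  }
})
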