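# Shared fixture builders. Everything is generated in code at test time.

# Small, quiet cohort configuration for fast deterministic tests.
quiet_config <- function(n_subjects = 1, n_epochs = 20, seed = 11,
                         noise_sd_pct = 0, artifact_rate_per_epoch = 0,
                         trait_sd_pct = 0, ...) {
  ftcd_config(n_subjects = n_subjects, n_epochs = n_epochs, seed = seed,
              noise_sd_pct = noise_sd_pct,
              artifact_rate_per_epoch = artifact_rate_per_epoch,
              trait_sd_pct = trait_sd_pct, ...)
}

# One noise-free session with given per-hemisphere amplitudes.
quiet_session <- function(amp_left = 4, amp_right = 2, seed = 11,
                          n_epochs = 20, baseline = 50, heart_rate = 60,
                          ...) {
  cfg <- quiet_config(n_epochs = n_epochs, ...)
  set.seed(seed)
  simulate_session(cfg,
                   list(subject_id = "T01", amp_left_pct = amp_left,
                        amp_right_pct = amp_right, baseline_cm_s = baseline,
                        heart_rate_bpm = heart_rate),
                   task_label = "language")
}

# A session that is a pure cardiac carrier (no task response, no noise).
carrier_session <- function(duration_s = 120, heart_rate = 60,
                            baseline = 50, fs = 25, pulsatility = 0.5) {
  t <- seq(0, duration_s, by = 1 / fs)
  v <- cardiac_waveform(t, heart_rate, baseline, pulsatility)
  ev <- data.frame(onset_s = c(0, 20, duration_s - 30),
                   kind = c("control", "target", "control"),
                   stringsAsFactors = FALSE)
  structure(list(subject_id = "C01", task_label = "carrier",
                 sample_rate_hz = fs, time_s = t, left_velocity = v,
                 right_velocity = v, events = ev, baseline_cm_s = baseline,
                 heart_rate_bpm = heart_rate),
            class = "ftcd_session")
}

# Build an ftcd_epochs object directly from dv matrices (time x epoch).
manual_epochs <- function(dv_left, dv_right = dv_left, fs = 25,
                          time_axis = NULL) {
  n_ep <- ncol(dv_left)
  if (is.null(time_axis)) {
    time_axis <- (seq_len(nrow(dv_left)) - 1) / fs
  }
  structure(list(time_axis_s = time_axis, dv_left_pct = dv_left,
                 dv_right_pct = dv_right,
                 baseline_left_cm_s = rep(50, n_ep),
                 baseline_right_cm_s = rep(50, n_ep),
                 good_flag = rep(TRUE, n_ep),
                 bad_reason = rep(NA_character_, n_ep),
                 n_total = n_ep, n_good = n_ep, subject_id = "M01",
                 task_label = "manual", sample_rate_hz = fs),
            class = "ftcd_epochs")
}
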