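# Synthetic bilateral CBFV cohort simulator.
#
# The carrier is an asymmetric periodic pulse (fast systolic upstroke over
# the first quarter cycle, slower exponential diastolic decay) whose cycle
# mean equals the baseline velocity exactly; task responses are multiplied
# in as percent modulations so downstream percent normalization recovers
# them; white noise and square artifact pulses are additive in percent of
# baseline.

# Within-cycle pulse shape on phase in [0, 1): raised-cosine upstroke over
# [0, 1/4), normalized exponential decay over [1/4, 1). Range [0, 1],
# continuous at the wrap (0 at both ends), peak at phase 1/4.
pulse_shape <- function(phase) {
  phase <- phase %% 1
  rise <- phase < 0.25
  out <- numeric(length(phase))
  out[rise] <- 0.5 - 0.5 * cos(4 * pi * phase[rise])
  E <- exp(-0.75 / 0.2)
  out[!rise] <- (exp(-(phase[!rise] - 0.25) / 0.2) - E) / (1 - E)
  out
}

# Analytic mean of pulse_shape over one period (used to centre the
# modulation so the cycle mean equals the baseline exactly).
pulse_shape_mean <- function() {
  E <- exp(-0.75 / 0.2)
  0.125 + 0.2 - 0.75 * E / (1 - E)
}

#' Pulsatile cardiac velocity carrier
#'
#' Generates the periodic Doppler-envelope carrier: a strictly positive
#' waveform with a sharp systolic rise and a slower diastolic decay, period
#' `60 / heart_rate_bpm` seconds, peak-to-trough modulation
#' `pulsatility_fraction * baseline_cm_s`, and a cycle mean equal to
#' `baseline_cm_s`.
#'
#' @param time_s Numeric vector of sample times in seconds.
#' @param heart_rate_bpm Heart rate in beats per minute (> 0).
#' @param baseline_cm_s Baseline (cycle-mean) velocity in cm/s (> 0).
#' @param pulsatility_fraction Peak-to-trough modulation as a fraction of
#'   baseline, in (0, 1). As it approaches 0 the output tends to the
#'   constant baseline.
#' @param phase0 Starting cardiac phase in cycles (default 0).
#' @return Numeric vector of velocities (cm/s), same length as `time_s`.
#' @examples
#' t <- seq(0, 5, by = 1 / 25)
#' v <- cardiac_waveform(t, heart_rate_bpm = 60, baseline_cm_s = 50,
#'                       pulsatility_fraction = 0.5)
#' mean(v[t < 1])  # ~ 50
#' @export
cardiac_waveform <- function(time_s, heart_rate_bpm, baseline_cm_s,
                             pulsatility_fraction, phase0 = 0) {
  if (!is.numeric(heart_rate_bpm) || heart_rate_bpm <= 0) {
    stop("heart_rate_bpm must be positive", call. = FALSE)
  }
  if (!is.numeric(baseline_cm_s) || baseline_cm_s <= 0) {
    stop("baseline_cm_s must be positive", call. = FALSE)
  }
  if (pulsatility_fraction < 0 || pulsatility_fraction >= 1) {
    stop("pulsatility_fraction must lie in [0, 1)", call. = FALSE)
  }
  phase <- phase0 + time_s * heart_rate_bpm / 60
  baseline_cm_s *
    (1 + pulsatility_fraction * (pulse_shape(phase) - pulse_shape_mean()))
}

#' Hemodynamic response shape
#'
#' Smooth unimodal task response in percent of baseline velocity: zero at
#' (and before) onset, a gamma-form rise peaking at exactly
#' `amplitude_pct` at `peak_delay_s`, then a Gaussian-tapered decay toward
#' a sustained plateau of `plateau_frac * amplitude_pct` that persists for
#' the remainder of the target interval.
#'
#' @param time_since_onset_s Numeric vector of times relative to task onset
#'   (seconds); negative times map to 0.
#' @param amplitude_pct Peak response amplitude in percent.
#' @param peak_delay_s Peak latency in seconds (> 0).
#' @param width_s Response width in seconds (> 0); sets both the rise
#'   full-width-at-half-maximum and the post-peak decay scale.
#' @param plateau_frac Sustained level after the peak as a fraction of the
#'   peak, in [0, 1).
#' @return Numeric vector of percent changes, same length as the input.
#' @examples
#' t <- seq(-2, 20, by = 0.04)
#' r <- hemodynamic_response(t, amplitude_pct = 5)
#' t[which.max(r)]  # 6 s
#' @export
hemodynamic_response <- function(time_since_onset_s, amplitude_pct,
                                 peak_delay_s = 6, width_s = 4,
                                 plateau_frac = 0.6) {
  if (peak_delay_s <= 0) stop("peak_delay_s must be positive", call. = FALSE)
  if (width_s <= 0) stop("width_s must be positive", call. = FALSE)
  if (plateau_frac < 0 || plateau_frac >= 1) {
    stop("plateau_frac must lie in [0, 1)", call. = FALSE)
  }
  t <- time_since_onset_s
  out <- numeric(length(t))
  # shape parameter matching a Gaussian of FWHM = width_s at the peak
  k <- (2.354820045 * peak_delay_s / width_s)^2
  rising <- t > 0 & t <= peak_delay_s
  out[rising] <- (t[rising] / peak_delay_s)^k *
    exp(k * (1 - t[rising] / peak_delay_s))
  falling <- t > peak_delay_s
  out[falling] <- plateau_frac + (1 - plateau_frac) *
    exp(-((t[falling] - peak_delay_s)^2) / (2 * width_s^2))
  amplitude_pct * out
}

new_session <- function(subject_id, task_label, sample_rate_hz, time_s,
                        left, right, events, baseline_cm_s = NA_real_,
                        heart_rate_bpm = NA_real_) {
  structure(
    list(subject_id = subject_id, task_label = task_label,
         sample_rate_hz = sample_rate_hz, time_s = time_s,
         left_velocity = left, right_velocity = right, events = events,
         baseline_cm_s = baseline_cm_s, heart_rate_bpm = heart_rate_bpm),
    class = "ftcd_session")
}

#' Validate a recording session
#'
#' Checks the structural invariants of an fTCD recording session: equal
#' channel lengths, strictly positive velocities, strictly increasing event
#' onsets with strictly alternating control/target kinds, and control
#' intervals at both ends (so every target has a full 5 s pre-onset
#' baseline).
#'
#' @param session An `ftcd_session` object.
#' @return The session, invisibly; errors on violation.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "ftcd_session"))
  if (length(session$left_velocity) != length(session$right_velocity)) {
    stop("left and right channels must have equal length", call. = FALSE)
  }
  if (any(session$left_velocity <= 0) || any(session$right_velocity <= 0)) {
    stop("velocities must be strictly positive", call. = FALSE)
  }
  ev <- session$events
  if (!all(c("onset_s", "kind") %in% names(ev))) {
    stop("events must have columns onset_s and kind", call. = FALSE)
  }
  if (is.unsorted(ev$onset_s, strictly = TRUE)) {
    stop("event onsets must be strictly increasing", call. = FALSE)
  }
  if (!all(ev$kind %in% c("target", "control"))) {
    stop("event kinds must be 'target' or 'control'", call. = FALSE)
  }
  if (any(ev$kind[-1] == ev$kind[-nrow(ev)])) {
    stop("event kinds must strictly alternate", call. = FALSE)
  }
  if (ev$kind[1] != "control" || ev$kind[nrow(ev)] != "control") {
    stop("first and last intervals must be controls", call. = FALSE)
  }
  invisible(session)
}

#' @export
print.ftcd_session <- function(x, ...) {
  n <- length(x$left_velocity)
  cat(sprintf("fTCD session %s / %s: %d samples at %g Hz (%.1f s), %d targets\n",
              x$subject_id, x$task_label, n, x$sample_rate_hz,
              n / x$sample_rate_hz, sum(x$events$kind == "target")))
  invisible(x)
}

#' Inject a square artifact pulse into a session
#'
#' Adds a contiguous rectangular offset of `amplitude_pct` percent of the
#' session baseline to one channel, emulating probe motion. Mainly useful
#' for constructing rejection test fixtures with known bad epochs.
#'
#' @param session An `ftcd_session`.
#' @param start_s Artifact start time in seconds.
#' @param duration_s Artifact duration in seconds.
#' @param amplitude_pct Signed amplitude in percent of the baseline velocity.
#' @param channel `"left"` or `"right"`.
#' @return The modified session.
#' @export
inject_artifact <- function(session, start_s, duration_s, amplitude_pct,
                            channel = c("left", "right")) {
  channel <- match.arg(channel)
  base <- session$baseline_cm_s
  if (is.na(base)) {
    base <- stats::median(session$left_velocity)
  }
  idx <- which(session$time_s >= start_s &
                 session$time_s < start_s + duration_s)
  field <- paste0(channel, "_velocity")
  session[[field]][idx] <- session[[field]][idx] + base * amplitude_pct / 100
  session
}

# Draw alternating control/target interval durations and return the event
# table plus the total session duration. Controls bracket the block.
draw_events <- function(config) {
  n <- config$n_epochs
  ctrl <- stats::runif(n + 1, config$control_duration_range_s[1],
                       config$control_duration_range_s[2])
  targ <- stats::runif(n, config$target_duration_range_s[1],
                       config$target_duration_range_s[2])
  durs <- numeric(2 * n + 1)
  durs[seq(1, 2 * n + 1, by = 2)] <- ctrl
  durs[seq(2, 2 * n, by = 2)] <- targ
  onsets <- c(0, cumsum(durs[-length(durs)]))
  kinds <- rep(c("control", "target"), length.out = 2 * n + 1)
  list(events = data.frame(onset_s = onsets, kind = kinds,
                           stringsAsFactors = FALSE),
       durations_s = durs,
       total_s = sum(durs))
}

#' Simulate one recording session
#'
#' Generates a bilateral CBFV recording for one subject performing one task:
#' a pulsatile cardiac carrier with slow (+/- 5%) heart-rate drift,
#' multiplicative hemodynamic responses confined to target intervals (with
#' per-hemisphere amplitudes from `subject_state`), additive white
#' measurement noise, and (with probability `artifact_rate_per_epoch` per
#' target epoch) one square artifact pulse of 0.5--2 s and random sign.
#'
#' @param config An [ftcd_config()] object.
#' @param subject_state List with `subject_id`, per-hemisphere injected
#'   amplitudes `amp_left_pct` / `amp_right_pct` (percent), and optionally
#'   `baseline_cm_s` and `heart_rate_bpm` (drawn from the config ranges when
#'   absent).
#' @param task_label Task identifier (one of `config$tasks`).
#' @param seed Optional integer seed for standalone use; inside
#'   [simulate_cohort()] the cohort seed governs and this stays `NULL`.
#' @return An `ftcd_session` with attribute `"artifact_epochs"` listing the
#'   1-based indices of target epochs that received an injected artifact.
#' @export
simulate_session <- function(config, subject_state, task_label, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate_hz

  ev <- draw_events(config)
  n_samp <- floor(ev$total_s * fs) + 1L
  time_s <- (seq_len(n_samp) - 1L) / fs

  base <- subject_state$baseline_cm_s
  if (is.null(base) || is.na(base)) {
    base <- stats::runif(1, config$baseline_velocity_cm_s_range[1],
                         config$baseline_velocity_cm_s_range[2])
  }
  hr0 <- subject_state$heart_rate_bpm
  if (is.null(hr0) || is.na(hr0)) {
    hr0 <- stats::runif(1, config$heart_rate_bpm_range[1],
                        config$heart_rate_bpm_range[2])
  }

  # slow sinusoidal heart-rate drift (+/- 5%, ~1 min period, random phase);
  # cardiac phase is the cumulative integral of the instantaneous rate
  drift_phi <- stats::runif(1, 0, 2 * pi)
  hr_t <- hr0 * (1 + 0.05 * sin(2 * pi * time_s / 60 + drift_phi))
  phase <- cumsum(hr_t / 60) / fs
  carrier <- base * (1 + config$pulsatility_fraction *
                       (pulse_shape(phase) - pulse_shape_mean()))

  # percent modulation per channel: responses on targets only
  targets <- which(ev$events$kind == "target")
  mod_l <- numeric(n_samp)
  mod_r <- numeric(n_samp)
  for (k in targets) {
    onset <- ev$events$onset_s[k]
    dur <- ev$durations_s[k]
    span <- which(time_s >= onset & time_s <= onset + dur + 10)
    tr <- time_s[span] - onset
    shape <- hemodynamic_response(tr, 1, config$hrf_peak_delay_s,
                                  config$hrf_width_s, config$hrf_plateau_frac)
    # taper the response back to baseline after the target offset
    taper <- ifelse(tr > dur, exp(-((tr - dur) / 3)^2), 1)
    shape <- shape * taper
    mod_l[span] <- mod_l[span] + subject_state$amp_left_pct * shape
    mod_r[span] <- mod_r[span] + subject_state$amp_right_pct * shape
    if (config$initial_dip_pct > 0) {
      # brief bilateral dip just after onset (off by default)
      dip <- config$initial_dip_pct * exp(-((tr - 1) / 0.8)^2) * (tr > 0)
      mod_l[span] <- mod_l[span] - dip
      mod_r[span] <- mod_r[span] - dip
    }
  }

  left <- carrier * (1 + mod_l / 100)
  right <- carrier * (1 + mod_r / 100)

  if (config$noise_sd_pct > 0) {
    left <- left + base * stats::rnorm(n_samp, 0, config$noise_sd_pct) / 100
    right <- right + base * stats::rnorm(n_samp, 0, config$noise_sd_pct) / 100
  }

  sess <- new_session(subject_state$subject_id, task_label, fs, time_s,
                      left, right, ev$events, baseline_cm_s = base,
                      heart_rate_bpm = hr0)

  artifact_epochs <- integer(0)
  if (config$artifact_rate_per_epoch > 0) {
    hit <- stats::runif(length(targets)) < config$artifact_rate_per_epoch
    for (j in which(hit)) {
      onset <- ev$events$onset_s[targets[j]]
      a_dur <- stats::runif(1, config$artifact_duration_range_s[1],
                            config$artifact_duration_range_s[2])
      a_start <- onset + stats::runif(1, 1, 18 - a_dur)
      a_sign <- sample(c(-1, 1), 1)
      a_chan <- sample(c("left", "right"), 1)
      sess <- inject_artifact(sess, a_start, a_dur,
                              a_sign * config$artifact_amplitude_pct, a_chan)
      artifact_epochs <- c(artifact_epochs, j)
    }
  }
  attr(sess, "artifact_epochs") <- artifact_epochs
  validate_session(sess)
  sess
}

#' Simulate a two-task cohort with known ground truth
#'
#' Draws a subject-level lateralization trait shared (with correlation
#' `trait_cross_task_correlation`) across the two tasks, converts it into
#' per-hemisphere response amplitudes, and simulates one session per subject
#' and task. All randomness flows from `config$seed`, so identical configs
#' give bit-identical cohorts.
#'
#' The trait model for subject i uses a latent standard-normal draw `z_i`
#' and task-specific innovations: `u_task = sqrt(|rho|) * sgn * z_i +
#' sqrt(1 - |rho|) * e_task` (with `sgn = sign(rho)` applied to the second
#' task), so that `cor(u_A, u_B) = rho` in the population. The injected
#' left-minus-right amplitude for each task is then
#' `effect_left - effect_right + trait_sd_pct * u_task`.
#'
#' @param config An [ftcd_config()] object.
#' @return A list with elements `sessions` (named list of `ftcd_session`,
#'   `"<subject>_<task>"`) and `truth` (data frame with columns
#'   `subject_id`, `task_label`, `true_delta_v_pct`, `latent_trait`,
#'   `amp_left_pct`, `amp_right_pct`).
#' @examples
#' cohort <- simulate_cohort(ftcd_config(n_subjects = 2, seed = 7))
#' cohort$truth
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  rho <- config$trait_cross_task_correlation
  z <- stats::rnorm(n)
  e1 <- stats::rnorm(n)
  e2 <- stats::rnorm(n)
  s <- sqrt(abs(rho))
  u <- cbind(s * z + sqrt(1 - abs(rho)) * e1,
             sign(rho + (rho == 0)) * s * z + sqrt(1 - abs(rho)) * e2)

  ids <- sprintf("S%02d", seq_len(n))
  baselines <- stats::runif(n, config$baseline_velocity_cm_s_range[1],
                            config$baseline_velocity_cm_s_range[2])
  heart_rates <- stats::runif(n, config$heart_rate_bpm_range[1],
                              config$heart_rate_bpm_range[2])

  sessions <- list()
  truth <- vector("list", n * 2)
  row <- 0L
  for (i in seq_len(n)) {
    for (k in seq_along(config$tasks)) {
      task <- config$tasks[k]
      amp_l <- config$effect_left_pct[[task]] +
        config$trait_sd_pct * u[i, k] / 2
      amp_r <- config$effect_right_pct[[task]] -
        config$trait_sd_pct * u[i, k] / 2
      st <- list(subject_id = ids[i], amp_left_pct = amp_l,
                 amp_right_pct = amp_r, baseline_cm_s = baselines[i],
                 heart_rate_bpm = heart_rates[i])
      sess <- simulate_session(config, st, task)
      sessions[[paste(ids[i], task, sep = "_")]] <- sess
      row <- row + 1L
      truth[[row]] <- data.frame(
        subject_id = ids[i], task_label = task,
        true_delta_v_pct = amp_l - amp_r, latent_trait = z[i],
        amp_left_pct = amp_l, amp_right_pct = amp_r,
        stringsAsFactors = FALSE)
    }
  }
  list(sessions = sessions, truth = do.call(rbind, truth))
}
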