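#' Simulation configuration for a synthetic fTCD cohort
#'
#' Builds and validates the parameter set that drives [simulate_cohort()] and
#' [simulate_session()]. Defaults follow the standard event-related fTCD
#' block design: twenty target/control epochs per block, target intervals of
#' 25--35 s (mean 30 s) alternating with control intervals of 15--25 s
#' (mean 20 s), and envelope velocities sampled at 25 Hz.
#'
#' Hemodynamic task responses are injected per hemisphere. For each task the
#' mean percent-change amplitudes are `effect_left_pct` / `effect_right_pct`;
#' on top of these a subject-level lateralization trait (SD `trait_sd_pct`,
#' correlated `trait_cross_task_correlation` across the two tasks) shifts the
#' left/right amplitudes in opposite directions, so the injected
#' left-minus-right amplitude for subject i in task k is
#' `effect_left_pct[k] - effect_right_pct[k] + trait_sd_pct * u_ik`.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param sample_rate_hz Envelope sample rate in Hz.
#' @param n_epochs Target epochs per session.
#' @param target_duration_range_s,control_duration_range_s Uniform sampling
#'   ranges (seconds) for target and control interval durations.
#' @param heart_rate_bpm_range Range of subject resting heart rates
#'   (beats/min); the instantaneous rate drifts slowly (+/- 5%) within a
#'   session.
#' @param baseline_velocity_cm_s_range Range of subject baseline middle
#'   cerebral artery velocities (cm/s).
#' @param pulsatility_fraction Peak-to-trough cardiac modulation as a
#'   fraction of baseline velocity, in (0, 1).
#' @param hrf_peak_delay_s,hrf_width_s Peak latency and width (seconds) of
#'   the hemodynamic response shape, see [hemodynamic_response()].
#' @param hrf_plateau_frac Sustained plateau level after the peak, as a
#'   fraction of the peak amplitude.
#' @param tasks Character vector of the two task labels.
#' @param effect_left_pct,effect_right_pct Named numeric vectors (one entry
#'   per task, or a scalar recycled) of mean hemodynamic amplitudes in
#'   percent of baseline velocity.
#' @param trait_sd_pct Between-subject SD (percent) of the lateralization
#'   trait.
#' @param trait_cross_task_correlation Population correlation, in [-1, 1],
#'   of the trait across the two tasks.
#' @param noise_sd_pct SD of white measurement noise, percent of baseline.
#' @param artifact_rate_per_epoch Probability that a target epoch receives
#'   one contiguous artifact.
#' @param artifact_amplitude_pct Artifact amplitude in percent of baseline;
#'   must exceed 30 so injected artifacts trip the +/- 30% rejection rule.
#' @param artifact_duration_range_s Uniform range (seconds) of artifact
#'   durations.
#' @param initial_dip_pct Depth (percent, >= 0) of an optional brief
#'   bilateral dip just after task onset; 0 disables it.
#' @param seed Integer seed; all cohort randomness derives from it.
#'
#' @return An object of class `ftcd_config` (a validated named list).
#' @examples
#' cfg <- ftcd_config(n_subjects = 2, seed = 42)
#' cfg$n_epochs
#' @export
ftcd_config <- function(n_subjects = 10,
                        sample_rate_hz = 25,
                        n_epochs = 20,
                        target_duration_range_s = c(25, 35),
                        control_duration_range_s = c(15, 25),
                        heart_rate_bpm_range = c(55, 85),
                        baseline_velocity_cm_s_range = c(45, 65),
                        pulsatility_fraction = 0.5,
                        hrf_peak_delay_s = 6,
                        hrf_width_s = 4,
                        hrf_plateau_frac = 0.6,
                        tasks = c("language", "knapping"),
                        effect_left_pct = c(language = 5.0, knapping = 2.6),
                        effect_right_pct = c(language = 2.5, knapping = 5.0),
                        trait_sd_pct = 2.5,
                        trait_cross_task_correlation = 0.74,
                        noise_sd_pct = 4,
                        artifact_rate_per_epoch = 0.1,
                        artifact_amplitude_pct = 50,
                        artifact_duration_range_s = c(0.5, 2),
                        initial_dip_pct = 0,
                        seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    sample_rate_hz = sample_rate_hz,
    n_epochs = as.integer(n_epochs),
    target_duration_range_s = as.numeric(target_duration_range_s),
    control_duration_range_s = as.numeric(control_duration_range_s),
    heart_rate_bpm_range = as.numeric(heart_rate_bpm_range),
    baseline_velocity_cm_s_range = as.numeric(baseline_velocity_cm_s_range),
    pulsatility_fraction = pulsatility_fraction,
    hrf_peak_delay_s = hrf_peak_delay_s,
    hrf_width_s = hrf_width_s,
    hrf_plateau_frac = hrf_plateau_frac,
    tasks = as.character(tasks),
    effect_left_pct = expand_per_task(effect_left_pct, tasks),
    effect_right_pct = expand_per_task(effect_right_pct, tasks),
    trait_sd_pct = trait_sd_pct,
    trait_cross_task_correlation = trait_cross_task_correlation,
    noise_sd_pct = noise_sd_pct,
    artifact_rate_per_epoch = artifact_rate_per_epoch,
    artifact_amplitude_pct = artifact_amplitude_pct,
    artifact_duration_range_s = as.numeric(artifact_duration_range_s),
    initial_dip_pct = initial_dip_pct,
    seed = as.integer(seed)
  )
  class(cfg) <- "ftcd_config"
  validate_config(cfg)
  cfg
}

expand_per_task <- function(x, tasks) {
  x <- as.numeric(unlist(x))
  if (length(x) == 1L) x <- rep(x, length(tasks))
  if (length(x) != length(tasks)) {
    stop("per-task effect must have length 1 or one value per task",
         call. = FALSE)
  }
  names(x) <- tasks
  x
}

validate_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_msg(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  stopifnot_msg(cfg$sample_rate_hz > 0, "sample_rate_hz must be positive")
  stopifnot_msg(cfg$n_epochs >= 1, "n_epochs must be >= 1")
  for (rng in list(cfg$target_duration_range_s, cfg$control_duration_range_s,
                   cfg$heart_rate_bpm_range, cfg$baseline_velocity_cm_s_range,
                   cfg$artifact_duration_range_s)) {
    stopifnot_msg(length(rng) == 2 && all(rng > 0) && rng[1] <= rng[2],
                  "duration/rate ranges must be positive with lo <= hi")
  }
  stopifnot_msg(cfg$pulsatility_fraction > 0 && cfg$pulsatility_fraction < 1,
                "pulsatility_fraction must lie in (0, 1)")
  stopifnot_msg(cfg$hrf_peak_delay_s > 0, "hrf_peak_delay_s must be positive")
  stopifnot_msg(cfg$hrf_width_s > 0, "hrf_width_s must be positive")
  stopifnot_msg(cfg$hrf_plateau_frac >= 0 && cfg$hrf_plateau_frac < 1,
                "hrf_plateau_frac must lie in [0, 1)")
  stopifnot_msg(length(cfg$tasks) == 2 && !anyDuplicated(cfg$tasks),
                "exactly two distinct task labels are required")
  stopifnot_msg(cfg$trait_sd_pct >= 0, "trait_sd_pct must be >= 0")
  stopifnot_msg(abs(cfg$trait_cross_task_correlation) <= 1,
                "trait_cross_task_correlation must lie in [-1, 1]")
  stopifnot_msg(cfg$noise_sd_pct >= 0, "noise_sd_pct must be >= 0")
  stopifnot_msg(cfg$artifact_rate_per_epoch >= 0 &&
                  cfg$artifact_rate_per_epoch <= 1,
                "artifact_rate_per_epoch must be a probability")
  stopifnot_msg(cfg$artifact_amplitude_pct > 30,
                "artifact_amplitude_pct must exceed 30 (the rejection threshold)")
  stopifnot_msg(cfg$initial_dip_pct >= 0, "initial_dip_pct must be >= 0")
  invisible(cfg)
}

#' @export
print.ftcd_config <- function(x, ...) {
  cat("fTCD cohort simulation configuration\n")
  cat(sprintf("  %d subjects x tasks [%s], %d epochs/session at %g Hz\n",
              x$n_subjects, paste(x$tasks, collapse = ", "),
              x$n_epochs, x$sample_rate_hz))
  cat(sprintf("  effects L/R (%%): %s\n",
              paste(sprintf("%s %.1f/%.1f", x$tasks, x$effect_left_pct,
                            x$effect_right_pct), collapse = "; ")))
  cat(sprintf("  trait sd %.2f%%, cross-task rho %.2f, noise sd %.2f%%\n",
              x$trait_sd_pct, x$trait_cross_task_correlation, x$noise_sd_pct))
  cat(sprintf("  artifacts: rate %.2f/epoch, amplitude %.0f%%\n",
              x$artifact_rate_per_epoch, x$artifact_amplitude_pct))
  invisible(x)
}
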