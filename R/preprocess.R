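# Preprocessing chain: Doppler envelope -> cardiac-cycle means ->
# baseline-normalized epochs -> artifact screening -> filtered averages.

#' Detect cardiac cycles in a recording
#'
#' Finds systolic peaks on the left channel (the reference channel: both
#' middle cerebral arteries share the same heart, so one set of cycle
#' boundaries applies to both), places cycle boundaries at the diastolic
#' minima between successive peaks, and computes per-cycle mean velocities
#' for both channels over identical boundaries. Cycles with physiologically
#' implausible durations (outside 60/200 to 60/30 s, i.e. 30--200 bpm) are
#' discarded.
#'
#' @param session An `ftcd_session` with at least 10 s of signal.
#' @return An object of class `ftcd_beats`: list with `cycles` (data frame
#'   `start_s`, `end_s`, `mid_s`, `duration_s`, `mean_left`, `mean_right`)
#'   and `cycle_boundaries_s`.
#' @export
detect_cardiac_cycles <- function(session) {
  stopifnot(inherits(session, "ftcd_session"))
  fs <- session$sample_rate_hz
  x <- session$left_velocity
  n <- length(x)
  if (n < 10 * fs) stop("need at least 10 s of signal", call. = FALSE)

  if (max(x) - min(x) < 1e-9 * max(abs(x), 1)) {
    stop("no cardiac signal detected", call. = FALSE)
  }
  min_dist <- max(2L, round(0.3 * fs))
  # systolic peaks: local maxima above the median, >= 0.3 s apart
  med <- stats::median(x)
  mid <- x[2:(n - 1L)]
  cand <- 1L + which(mid > x[1:(n - 2L)] & mid >= x[3:n] & mid > med)
  if (length(cand) < 6) stop("no cardiac signal detected", call. = FALSE)
  peaks <- cand[1]
  last <- cand[1]
  for (i in cand[-1]) {
    if (i - last >= min_dist) {
      peaks <- c(peaks, i)
      last <- i
    }
  }
  if (length(peaks) < 6) stop("no cardiac signal detected", call. = FALSE)

  # boundary = diastolic minimum between consecutive systolic peaks
  bounds <- vapply(seq_len(length(peaks) - 1L), function(i) {
    seg <- peaks[i]:peaks[i + 1]
    seg[which.min(x[seg])]
  }, integer(1))

  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  dur <- (ends - starts) / fs
  ok <- dur >= 60 / 200 & dur <= 60 / 30
  starts <- starts[ok]; ends <- ends[ok]
  if (length(starts) < 5) stop("no cardiac signal detected", call. = FALSE)

  # per-cycle means over [start, end) from cumulative sums
  cs_l <- c(0, cumsum(session$left_velocity))
  cs_r <- c(0, cumsum(session$right_velocity))
  n_in_cycle <- ends - starts
  mean_l <- (cs_l[ends] - cs_l[starts]) / n_in_cycle
  mean_r <- (cs_r[ends] - cs_r[starts]) / n_in_cycle

  t <- session$time_s
  cycles <- data.frame(
    start_s = t[starts], end_s = t[ends],
    mid_s = (t[starts] + t[ends]) / 2,
    duration_s = (ends - starts) / fs,
    mean_left = mean_l, mean_right = mean_r)
  structure(list(cycles = cycles,
                 cycle_boundaries_s = sort(unique(c(t[starts], t[ends])))),
            class = "ftcd_beats")
}

#' Replace the pulsatile envelope by interpolated cycle means
#'
#' Removes cardiac pulsatility while preserving the slow hemodynamics:
#' each channel is replaced by its per-cycle means, linearly interpolated
#' at the cycle midpoints and resampled on the original time grid. Values
#' before the first and after the last midpoint are held constant.
#'
#' @param session An `ftcd_session`.
#' @param beats The `ftcd_beats` from [detect_cardiac_cycles()].
#' @return An `ftcd_session` on the same grid with smoothed channels.
#' @export
integrate_cardiac <- function(session, beats) {
  stopifnot(inherits(session, "ftcd_session"), inherits(beats, "ftcd_beats"))
  cy <- beats$cycles
  session$left_velocity <- stats::approx(cy$mid_s, cy$mean_left,
                                         xout = session$time_s,
                                         rule = 2)$y
  session$right_velocity <- stats::approx(cy$mid_s, cy$mean_right,
                                          xout = session$time_s,
                                          rule = 2)$y
  attr(session, "cardiac_integrated") <- TRUE
  session
}

#' Segment a session into baseline-normalized target epochs
#'
#' Extracts a window of `[-pre_s, +post_s]` seconds around every target
#' onset, computes the per-epoch baseline velocity `V_b` for each channel
#' as the mean over the `pre_s` seconds of control immediately preceding
#' the onset, and converts each channel to percent change
#' `dv(t) = 100 * (V(t) - V_b) / V_b`. Targets without `pre_s` seconds of
#' preceding or `post_s` seconds of following signal are dropped with a
#' warning; epochs with a non-positive baseline are marked bad with reason
#' `"invalid baseline"`.
#'
#' @param session An `ftcd_session` (normally after [integrate_cardiac()]).
#' @param pre_s Baseline span before onset, seconds (default 5).
#' @param post_s Window extent after onset, seconds (default 25).
#' @return An object of class `ftcd_epochs`: `time_axis_s`, matrices
#'   `dv_left_pct` / `dv_right_pct` (time x epoch), per-epoch baselines,
#'   `good_flag`, `bad_reason`, counts `n_total` / `n_good`.
#' @export
segment_epochs <- function(session, pre_s = 5, post_s = 25) {
  stopifnot(inherits(session, "ftcd_session"))
  fs <- session$sample_rate_hz
  n <- length(session$left_velocity)
  pre_n <- round(pre_s * fs)
  post_n <- round(post_s * fs)
  rel <- (-pre_n):post_n
  time_axis <- rel / fs

  onsets <- session$events$onset_s[session$events$kind == "target"]
  keep <- logical(length(onsets))
  centers <- integer(length(onsets))
  for (j in seq_along(onsets)) {
    i0 <- round(onsets[j] * fs) + 1L   # sample index of t = 0
    if (i0 - pre_n >= 1L && i0 + post_n <= n) {
      keep[j] <- TRUE
      centers[j] <- i0
    }
  }
  if (any(!keep)) {
    warning(sprintf("dropped %d target epoch(s) without a full [-%g, +%g] s window",
                    sum(!keep), pre_s, post_s), call. = FALSE)
  }
  centers <- centers[keep]
  n_ep <- length(centers)
  dv_l <- matrix(NA_real_, length(rel), n_ep)
  dv_r <- matrix(NA_real_, length(rel), n_ep)
  base_l <- numeric(n_ep)
  base_r <- numeric(n_ep)
  good <- rep(TRUE, n_ep)
  reason <- rep(NA_character_, n_ep)
  bl_idx <- seq_len(pre_n)   # rows of the window with t in [-pre_s, 0)

  for (j in seq_len(n_ep)) {
    idx <- centers[j] + rel
    vl <- session$left_velocity[idx]
    vr <- session$right_velocity[idx]
    base_l[j] <- mean(vl[bl_idx])
    base_r[j] <- mean(vr[bl_idx])
    if (base_l[j] <= 0 || base_r[j] <= 0) {
      good[j] <- FALSE
      reason[j] <- "invalid baseline"
      dv_l[, j] <- NA_real_
      dv_r[, j] <- NA_real_
    } else {
      dv_l[, j] <- 100 * (vl - base_l[j]) / base_l[j]
      dv_r[, j] <- 100 * (vr - base_r[j]) / base_r[j]
    }
  }
  structure(list(time_axis_s = time_axis, dv_left_pct = dv_l,
                 dv_right_pct = dv_r, baseline_left_cm_s = base_l,
                 baseline_right_cm_s = base_r, good_flag = good,
                 bad_reason = reason, n_total = n_ep, n_good = sum(good),
                 subject_id = session$subject_id,
                 task_label = session$task_label,
                 sample_rate_hz = fs),
            class = "ftcd_epochs")
}

#' Flag epochs with implausible velocity excursions
#'
#' Marks an epoch bad when the absolute percent change exceeds
#' `threshold_pct` anywhere in the window on either channel (strict
#' inequality: an excursion of exactly the threshold is kept). Epochs
#' already marked bad (e.g. invalid baseline) stay bad. Idempotent.
#'
#' @param epochs An `ftcd_epochs`.
#' @param threshold_pct Rejection threshold in percent (default 30).
#' @return The `ftcd_epochs` with updated `good_flag`, `bad_reason` and
#'   `n_good`.
#' @export
reject_artifacts <- function(epochs, threshold_pct = 30) {
  stopifnot(inherits(epochs, "ftcd_epochs"))
  for (j in seq_len(epochs$n_total)) {
    if (!epochs$good_flag[j]) next
    peak <- max(abs(epochs$dv_left_pct[, j]), abs(epochs$dv_right_pct[, j]))
    if (peak > threshold_pct) {
      epochs$good_flag[j] <- FALSE
      epochs$bad_reason[j] <- "artifact"
    }
  }
  epochs$n_good <- sum(epochs$good_flag)
  epochs
}

#' Subject-level quality control
#'
#' A subject is retained only if every condition keeps at least
#' `min_good_frac` of its epochs; the boundary counts as good (the
#' exclusion rule is "less than", so 16/20 = 0.80 is retained).
#'
#' @param epoch_sets Named list of `ftcd_epochs`, one per condition.
#' @param min_good_frac Minimum good-epoch fraction (default 0.8).
#' @return List with `keep` (logical) and `report` (data frame
#'   `condition`, `n_total`, `n_good`, `fraction`, `pass`).
#' @export
qc_subject <- function(epoch_sets, min_good_frac = 0.8) {
  stopifnot(is.list(epoch_sets), length(epoch_sets) >= 1)
  conds <- names(epoch_sets)
  if (is.null(conds)) conds <- paste0("condition_", seq_along(epoch_sets))
  rows <- lapply(seq_along(epoch_sets), function(i) {
    es <- epoch_sets[[i]]
    stopifnot(inherits(es, "ftcd_epochs"))
    frac <- if (es$n_total == 0) 0 else es$n_good / es$n_total
    data.frame(condition = conds[i], n_total = es$n_total,
               n_good = es$n_good, fraction = frac,
               pass = es$n_total > 0 && frac >= min_good_frac,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(keep = all(report$pass), report = report)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass of the given order and applies it forward
#' and backward (zero phase lag, squared magnitude response: the gain at
#' the cutoff is 0.5 for a single-pass -3 dB design). The input is
#' extended by `pad_s` seconds of odd reflection at both ends before
#' filtering and trimmed afterwards, so that filter transients die out in
#' the padding rather than in the data.
#'
#' @param x Numeric vector.
#' @param sample_rate_hz Sample rate of `x` in Hz.
#' @param cutoff_hz Cutoff frequency in Hz (default 1).
#' @param order Filter order for each pass (default 2).
#' @param pad_s Reflection padding in seconds (default 5).
#' @return Filtered vector, same length as `x`.
#' @export
zero_phase_butter <- function(x, sample_rate_hz, cutoff_hz = 1, order = 2,
                              pad_s = 5) {
  n <- length(x)
  if (n < 3) stop("signal too short to filter", call. = FALSE)
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate_hz / 2) {
    stop("cutoff_hz must lie in (0, Nyquist)", call. = FALSE)
  }
  p <- min(round(pad_s * sample_rate_hz), n - 1L)
  left_pad <- 2 * x[1] - x[(p + 1L):2]
  right_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
  xp <- c(left_pad, x, right_pad)
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2))
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(p + 1L):(p + n)]
}

#' Average good epochs and low-pass filter the mean response
#'
#' Averages the good epochs pointwise per channel, then applies the
#' zero-phase Butterworth low-pass ([zero_phase_butter()]) to each mean
#' trace. Averaging precedes filtering.
#'
#' @param epochs An `ftcd_epochs` (after [reject_artifacts()]).
#' @param cutoff_hz Low-pass cutoff in Hz (default 1).
#' @param order Butterworth order (default 2).
#' @return An object of class `ftcd_response`: `time_axis_s`,
#'   `mean_dv_left_pct`, `mean_dv_right_pct`, `n_good_epochs`,
#'   `subject_id`, `task_label`, `sample_rate_hz`.
#' @export
average_and_filter <- function(epochs, cutoff_hz = 1, order = 2) {
  stopifnot(inherits(epochs, "ftcd_epochs"))
  good <- which(epochs$good_flag)
  if (length(good) == 0) stop("no usable epochs", call. = FALSE)
  ml <- rowMeans(epochs$dv_left_pct[, good, drop = FALSE])
  mr <- rowMeans(epochs$dv_right_pct[, good, drop = FALSE])
  fs <- epochs$sample_rate_hz
  structure(list(time_axis_s = epochs$time_axis_s,
                 mean_dv_left_pct = zero_phase_butter(ml, fs, cutoff_hz, order),
                 mean_dv_right_pct = zero_phase_butter(mr, fs, cutoff_hz, order),
                 n_good_epochs = length(good),
                 subject_id = epochs$subject_id,
                 task_label = epochs$task_label,
                 sample_rate_hz = fs),
            class = "ftcd_response")
}

#' Run the full preprocessing chain on one session
#'
#' Convenience wrapper: [detect_cardiac_cycles()] ->
#' [integrate_cardiac()] -> [segment_epochs()] -> [reject_artifacts()] ->
#' [average_and_filter()].
#'
#' @param session An `ftcd_session`.
#' @param cutoff_hz,order Filter settings, see [average_and_filter()].
#' @param threshold_pct Artifact rejection threshold in percent.
#' @param pre_s,post_s Epoch window, see [segment_epochs()].
#' @return List with `epochs` (the screened `ftcd_epochs`) and `response`
#'   (the `ftcd_response`).
#' @export
preprocess_session <- function(session, cutoff_hz = 1, order = 2,
                               threshold_pct = 30, pre_s = 5, post_s = 25) {
  beats <- detect_cardiac_cycles(session)
  smooth <- integrate_cardiac(session, beats)
  ep <- segment_epochs(smooth, pre_s = pre_s, post_s = post_s)
  ep <- reject_artifacts(ep, threshold_pct = threshold_pct)
  list(epochs = ep, response = average_and_filter(ep, cutoff_hz, order))
}

#' @export
print.ftcd_epochs <- function(x, ...) {
  cat(sprintf("fTCD epochs %s / %s: %d/%d good, window [%g, %g] s\n",
              x$subject_id, x$task_label, x$n_good, x$n_total,
              min(x$time_axis_s), max(x$time_axis_s)))
  invisible(x)
}

#' @export
print.ftcd_response <- function(x, ...) {
  cat(sprintf("fTCD response %s / %s: %d good epochs, peak dv L %.2f%% R %.2f%%\n",
              x$subject_id, x$task_label, x$n_good_epochs,
              max(x$mean_dv_left_pct), max(x$mean_dv_right_pct)))
  invisible(x)
}
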