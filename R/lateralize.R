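# Left-minus-right difference trace and the signed lateralization index.

#' Left-minus-right lateralization trace
#'
#' Pointwise difference of the averaged, filtered percent-change traces:
#' `delta_v_pct(t) = mean_dv_left_pct(t) - mean_dv_right_pct(t)`. Positive
#' values indicate greater relative blood flow velocity increase in the
#' left middle cerebral artery. No filtering or rescaling is applied.
#'
#' @param response An `ftcd_response` (see [average_and_filter()]).
#' @return An object of class `ftcd_delta`: `time_axis_s`, `delta_v_pct`,
#'   `subject_id`, `task_label`, `sample_rate_hz`.
#' @export
delta_v <- function(response) {
  stopifnot(inherits(response, "ftcd_response"))
  if (length(response$mean_dv_left_pct) != length(response$mean_dv_right_pct) ||
      length(response$mean_dv_left_pct) != length(response$time_axis_s)) {
    stop("left/right traces must share one time grid", call. = FALSE)
  }
  structure(list(time_axis_s = response$time_axis_s,
                 delta_v_pct = response$mean_dv_left_pct -
                   response$mean_dv_right_pct,
                 subject_id = response$subject_id,
                 task_label = response$task_label,
                 sample_rate_hz = response$sample_rate_hz),
            class = "ftcd_delta")
}

#' Construct a lateralization trace directly
#'
#' Builds an `ftcd_delta` from a time axis and a difference trace, for
#' analyses that start from precomputed left-minus-right data.
#'
#' @param time_axis_s Numeric time axis (seconds, relative to task onset).
#' @param delta_v_pct Numeric difference trace (percent), same length.
#' @param subject_id,task_label Identifiers.
#' @return An `ftcd_delta`.
#' @export
as_delta_trace <- function(time_axis_s, delta_v_pct,
                           subject_id = "anon", task_label = "task") {
  stopifnot(length(time_axis_s) == length(delta_v_pct),
            !is.unsorted(time_axis_s, strictly = TRUE))
  fs <- 1 / stats::median(diff(time_axis_s))
  structure(list(time_axis_s = as.numeric(time_axis_s),
                 delta_v_pct = as.numeric(delta_v_pct),
                 subject_id = subject_id, task_label = task_label,
                 sample_rate_hz = fs),
            class = "ftcd_delta")
}

# Trapezoidal mean of a sampled trace over [lo, hi] (time average of the
# piecewise-linear interpolant); exact for piecewise-linear traces with
# nodes on the grid.
trapezoid_mean <- function(time_s, values, lo, hi) {
  sel <- time_s >= lo & time_s <= hi
  if (sum(sel) < 2) stop("integration window too narrow", call. = FALSE)
  t <- time_s[sel]
  v <- values[sel]
  pracma::trapz(t, v) / (t[length(t)] - t[1])
}

#' Signed lateralization index
#'
#' Locates the time of the peak absolute lateralization within the
#' activation window, then averages the signed difference trace over an
#' integration window of `t_int_s` seconds centered at that peak
#' (time-average of the piecewise-linear trace, i.e. trapezoidal
#' integration divided by the window length). A positive index indicates
#' left-hemisphere dominance. Ties at the peak resolve to the earliest
#' sample; if the peak lies within `t_int_s / 2` of the trace end, the
#' integration window is clipped to the trace rather than shifted.
#'
#' @param trace An `ftcd_delta`.
#' @param activation_window_s Length-2 numeric: the window (seconds after
#'   onset) searched for the peak (default `c(2, 18)`).
#' @param t_int_s Integration window length in seconds (default 2).
#' @return An object of class `ftcd_li`: `li_pct`, `t_max_s`, `window_s`
#'   (the realized integration window), `activation_window_s`, `t_int_s`,
#'   `subject_id`, `task_label`.
#' @examples
#' t <- seq(-5, 25, by = 0.04)
#' tri <- pmax(0, 5 * (1 - abs(t - 10) / 8)) * (t >= 2 & t <= 18)
#' li <- lateralization_index(as_delta_trace(t, tri))
#' li$li_pct   # 4.6875
#' @export
lateralization_index <- function(trace, activation_window_s = c(2, 18),
                                 t_int_s = 2) {
  stopifnot(inherits(trace, "ftcd_delta"))
  lo <- activation_window_s[1]
  hi <- activation_window_s[2]
  in_win <- which(trace$time_axis_s >= lo & trace$time_axis_s <= hi)
  if (length(in_win) == 0) stop("empty activation window", call. = FALSE)
  absdv <- abs(trace$delta_v_pct[in_win])
  t_max <- trace$time_axis_s[in_win[which.max(absdv)]]  # earliest on ties

  w_lo <- max(t_max - t_int_s / 2, min(trace$time_axis_s))
  w_hi <- min(t_max + t_int_s / 2, max(trace$time_axis_s))
  li <- trapezoid_mean(trace$time_axis_s, trace$delta_v_pct, w_lo, w_hi)
  structure(list(li_pct = li, t_max_s = t_max, window_s = c(w_lo, w_hi),
                 activation_window_s = activation_window_s,
                 t_int_s = t_int_s, subject_id = trace$subject_id,
                 task_label = trace$task_label),
            class = "ftcd_li")
}

#' @export
print.ftcd_li <- function(x, ...) {
  side <- if (x$li_pct > 0) "left" else if (x$li_pct < 0) "right" else "none"
  cat(sprintf("LI %s / %s: %+.3f%% (%s dominant), peak at %.2f s, window [%.2f, %.2f] s\n",
              x$subject_id, x$task_label, x$li_pct, side, x$t_max_s,
              x$window_s[1], x$window_s[2]))
  invisible(x)
}
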