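# Group-level statistics: mean lateralization traces with SEM bands,
# cross-task LI correlation, and the moving-window correlation of
# lateralization time courses across subjects.

check_common_grid <- function(traces) {
  t0 <- traces[[1]]$time_axis_s
  for (tr in traces[-1]) {
    if (length(tr$time_axis_s) != length(t0) ||
        max(abs(tr$time_axis_s - t0)) > 1e-9) {
      stop("all traces must share one time grid", call. = FALSE)
    }
  }
  t0
}

#' Group mean lateralization trace with SEM band
#'
#' Pointwise mean and standard error of the mean (sample SD across
#' subjects divided by `sqrt(n)`) of subject lateralization traces for one
#' task.
#'
#' @param traces List of `ftcd_delta` objects on a common grid (n >= 2).
#' @param task_label Optional label; defaults to the first trace's label.
#' @return An object of class `ftcd_group_trace`: data-frame-like list
#'   with `time_axis_s`, `mean_delta_v_pct`, `sem_delta_v_pct`,
#'   `n_subjects`, `task_label`.
#' @export
group_trace <- function(traces, task_label = NULL) {
  stopifnot(length(traces) >= 2)
  t0 <- check_common_grid(traces)
  m <- vapply(traces, function(tr) tr$delta_v_pct,
              numeric(length(t0)))
  structure(list(time_axis_s = t0,
                 mean_delta_v_pct = rowMeans(m),
                 sem_delta_v_pct = apply(m, 1, stats::sd) / sqrt(ncol(m)),
                 n_subjects = ncol(m),
                 task_label = task_label %||% traces[[1]]$task_label),
            class = "ftcd_group_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean lateralization over one analysis window
#'
#' Mean of the sampled trace over the half-open interval
#' `[start_s, start_s + length_s)`.
#'
#' @param trace An `ftcd_delta`.
#' @param start_s Window start in seconds.
#' @param length_s Window length in seconds.
#' @return The window mean (percent).
#' @export
window_mean <- function(trace, start_s, length_s) {
  stopifnot(inherits(trace, "ftcd_delta"))
  t <- trace$time_axis_s
  eps <- 1e-9
  if (start_s < t[1] - eps || start_s + length_s > t[length(t)] + eps) {
    stop("analysis window lies outside the trace span", call. = FALSE)
  }
  sel <- t >= start_s - eps & t < start_s + length_s - eps
  if (!any(sel)) stop("analysis window contains no samples", call. = FALSE)
  mean(trace$delta_v_pct[sel])
}

#' Critical Pearson correlation at a given significance level
#'
#' The absolute correlation above which the two-sided p-value (from the
#' t transform with `n - 2` degrees of freedom) falls below `alpha`.
#'
#' @param n_subjects Number of paired observations (>= 3).
#' @param alpha Two-sided significance level (default 0.05).
#' @return The critical |r|.
#' @examples
#' critical_r(10)  # 0.632
#' @export
critical_r <- function(n_subjects, alpha = 0.05) {
  if (n_subjects < 3) stop("need at least 3 subjects", call. = FALSE)
  df <- n_subjects - 2
  tc <- stats::qt(1 - alpha / 2, df)
  tc / sqrt(tc^2 + df)
}

# Pearson r column-wise between two (subjects x windows) matrices; windows
# with zero variance in either matrix yield NA.
columnwise_pearson <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

#' Moving-window cross-task correlation of lateralization
#'
#' For each window start offset, computes each subject's mean
#' lateralization over the window `[start, start + length)` in both tasks,
#' then the Pearson correlation across subjects between the two tasks'
#' window means, with an uncorrected two-sided p-value from the t
#' transform. Windows in which either task has zero variance across
#' subjects are recorded as missing (`NA`), not as zero.
#'
#' @param traces_a,traces_b Named lists of `ftcd_delta` (names = subject
#'   ids), one per task; subjects are paired by name (or by position when
#'   unnamed). n >= 3.
#' @param starts_s Window start offsets in seconds (default: every sample
#'   from -5 to 15 s at the trace sample rate).
#' @param length_s Window length in seconds (default 5).
#' @param alpha Significance level for the critical-r threshold
#'   (default 0.05).
#' @return An object of class `ftcd_wincor`: data frame `series`
#'   (`start_s`, `r`, `p`), plus `r_critical`, `n_subjects`,
#'   `window_length_s`, `alpha`, and the retained per-window subject means
#'   (`means_a`, `means_b`, subjects x windows).
#' @export
moving_window_correlation <- function(traces_a, traces_b, starts_s = NULL,
                                      length_s = 5, alpha = 0.05) {
  ids_a <- names(traces_a)
  ids_b <- names(traces_b)
  if (!is.null(ids_a) && !is.null(ids_b)) {
    if (!setequal(ids_a, ids_b)) {
      stop("both tasks must cover the same subjects", call. = FALSE)
    }
    traces_b <- traces_b[ids_a]
  } else if (length(traces_a) != length(traces_b)) {
    stop("both tasks must cover the same subjects", call. = FALSE)
  }
  n <- length(traces_a)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  t0 <- check_common_grid(c(traces_a, traces_b))
  if (is.null(starts_s)) {
    step <- 1 / traces_a[[1]]$sample_rate_hz
    starts_s <- seq(-5, 15, by = step)
  }

  wm <- function(traces) {
    m <- vapply(traces, function(tr) {
      vapply(starts_s, function(s0) window_mean(tr, s0, length_s), numeric(1))
    }, numeric(length(starts_s)))
    # vapply drops to a vector for a single window; keep subjects x windows
    if (is.null(dim(m))) m <- matrix(m, nrow = length(starts_s))
    t(m)
  }
  means_a <- wm(traces_a)
  means_b <- wm(traces_b)

  r <- columnwise_pearson(means_a, means_b)
  tv <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tv), n - 2)
  structure(list(series = data.frame(start_s = starts_s, r = r, p = p),
                 r_critical = critical_r(n, alpha), n_subjects = n,
                 window_length_s = length_s, alpha = alpha,
                 means_a = means_a, means_b = means_b,
                 subjects = ids_a %||% sprintf("S%02d", seq_len(n))),
            class = "ftcd_wincor")
}

#' Cross-task correlation of lateralization indices
#'
#' Pearson correlation between two tasks' subject LI values (paired by
#' position), with the two-sided p-value and the least-squares line of
#' task B on task A for scatter plotting.
#'
#' @param li_task_a,li_task_b Numeric vectors of per-subject LIs, paired,
#'   length >= 3.
#' @return List with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
li_correlation <- function(li_task_a, li_task_b) {
  a <- as.numeric(li_task_a)
  b <- as.numeric(li_task_b)
  if (length(a) != length(b)) stop("LI vectors must be paired", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("LI vectors must not contain NA", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  ct <- stats::cor.test(a, b, method = "pearson")
  fit <- stats::lm.fit(cbind(1, a), b)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = n)
}

#' @export
print.ftcd_wincor <- function(x, ...) {
  pk <- which.max(abs(x$series$r))
  cat(sprintf("moving-window correlation: %d subjects, %g s windows, %d offsets\n",
              x$n_subjects, x$window_length_s, nrow(x$series)))
  cat(sprintf("  peak |r| = %.3f at start %+.2f s (critical |r| = %.3f at alpha %.2f)\n",
              x$series$r[pk], x$series$start_s[pk], x$r_critical, x$alpha))
  invisible(x)
}

#' @export
print.ftcd_group_trace <- function(x, ...) {
  cat(sprintf("group trace %s: n = %d, mean delta V range [%.2f, %.2f]%%\n",
              x$task_label, x$n_subjects, min(x$mean_delta_v_pct),
              max(x$mean_delta_v_pct)))
  invisible(x)
}
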