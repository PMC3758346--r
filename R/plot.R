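# Base-graphics figures: bilateral response traces, group lateralization
# with SEM bands, and the moving-window correlation curve.

#' Plot a bilateral subject response
#'
#' Left (black) and right (red) mean percent-change traces against time
#' since task onset, with the baseline span marked.
#'
#' @param response An `ftcd_response`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_response <- function(response, ...) {
  t <- response$time_axis_s
  yl <- range(response$mean_dv_left_pct, response$mean_dv_right_pct)
  graphics::plot(t, response$mean_dv_left_pct, type = "l", col = "black",
                 xlab = "time since task onset (s)",
                 ylab = "CBFV change (%)", ylim = yl,
                 main = sprintf("%s / %s", response$subject_id,
                                response$task_label), ...)
  graphics::lines(t, response$mean_dv_right_pct, col = "red")
  graphics::abline(v = 0, lty = 3)
  graphics::segments(-5, yl[1], 0, yl[1], lwd = 3)
  graphics::legend("topleft", legend = c("left MCA", "right MCA"),
                   col = c("black", "red"), lty = 1, bty = "n")
}

#' Plot a group lateralization trace with SEM band
#'
#' @param gt An `ftcd_group_trace`.
#' @param add If `TRUE`, draw into the current plot.
#' @param col Line/band color.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_group_trace <- function(gt, add = FALSE, col = "black", ...) {
  t <- gt$time_axis_s
  lo <- gt$mean_delta_v_pct - gt$sem_delta_v_pct
  hi <- gt$mean_delta_v_pct + gt$sem_delta_v_pct
  if (!add) {
    graphics::plot(t, gt$mean_delta_v_pct, type = "n",
                   ylim = range(lo, hi),
                   xlab = "time since task onset (s)",
                   ylab = expression(Delta * "V (%)"), ...)
    graphics::abline(h = 0, lty = 3)
    graphics::abline(v = 0, lty = 3)
  }
  shade <- grDevices::adjustcolor(col, alpha.f = 0.25)
  graphics::polygon(c(t, rev(t)), c(lo, rev(hi)), col = shade, border = NA)
  graphics::lines(t, gt$mean_delta_v_pct, col = col, lwd = 2)
}

#' Plot the moving-window correlation curve
#'
#' Cross-task Pearson r as a function of window start offset, with the
#' uncorrected two-sided significance thresholds as horizontal lines.
#'
#' @param wc An `ftcd_wincor`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_window_correlation <- function(wc, ...) {
  graphics::plot(wc$series$start_s, wc$series$r, type = "l", lwd = 2,
                 ylim = c(-1, 1), xlab = "window start (s)",
                 ylab = "Pearson r", ...)
  graphics::abline(h = c(-wc$r_critical, wc$r_critical), lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = 0, lty = 3)
}

# Render the standard figure set for a completed pipeline run.
report_stage <- function(out_dir, fig_dir = file.path(out_dir, "figures")) {
  dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)
  group_dir <- file.path(out_dir, "group")

  gt_files <- list.files(group_dir, pattern = "^group_trace_.*\\.csv$",
                         full.names = TRUE)
  if (length(gt_files) > 0) {
    grDevices::png(file.path(fig_dir, "group_traces.png"), width = 800,
                   height = 500)
    cols <- c("black", "red", "blue")
    first <- TRUE
    for (i in seq_along(gt_files)) {
      df <- read_dialect(gt_files[i], c("time_s", "mean_dv", "sem"))
      gt <- structure(list(time_axis_s = df$time_s,
                           mean_delta_v_pct = df$mean_dv,
                           sem_delta_v_pct = df$sem,
                           n_subjects = NA_integer_,
                           task_label = sub("^group_trace_(.*)\\.csv$", "\\1",
                                            basename(gt_files[i]))),
                      class = "ftcd_group_trace")
      plot_group_trace(gt, add = !first, col = cols[(i - 1) %% 3 + 1])
      first <- FALSE
    }
    grDevices::dev.off()
  }

  wc_path <- file.path(group_dir, "window_correlation.csv")
  if (file.exists(wc_path)) {
    df <- read_dialect(wc_path, c("start_s", "r", "p", "r_critical", "n"))
    wc <- structure(list(series = df[, c("start_s", "r", "p")],
                         r_critical = df$r_critical[1],
                         n_subjects = df$n[1], window_length_s = NA_real_,
                         alpha = NA_real_),
                    class = "ftcd_wincor")
    grDevices::png(file.path(fig_dir, "window_correlation.png"), width = 800,
                   height = 500)
    plot_window_correlation(wc)
    grDevices::dev.off()
  }
  invisible(fig_dir)
}
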