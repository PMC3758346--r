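# CSV dialects for every pipeline artifact. All files are UTF-8 with a
# header row, '.' decimal separator and no thousands separators; times are
# in seconds. Numeric fields are written with 9 decimal places so a
# write-then-read round trip reproduces values to 1e-9.

fmt_num <- function(x) formatC(x, format = "f", digits = 9)

write_dialect <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_dialect <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("file %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  num_cols <- setdiff(required_cols, c("kind", "subject_id", "task_label"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && !anyNA(df[[cn]])) {
      stop(sprintf("file %s has non-numeric values in column %s", path, cn),
           call. = FALSE)
    }
    df[[cn]] <- v
  }
  df
}

session_paths <- function(dir, subject_id, task_label) {
  stem <- file.path(dir, paste(subject_id, task_label, sep = "_"))
  list(signal = paste0(stem, "_signal.csv"),
       events = paste0(stem, "_events.csv"))
}

#' Write a recording session as CSV
#'
#' Writes `<subject>_<task>_signal.csv` (columns `time_s`, `left_cm_s`,
#' `right_cm_s`) and `<subject>_<task>_events.csv` (columns `onset_s`,
#' `kind`) into `dir`.
#'
#' @param session An `ftcd_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ftcd_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- session_paths(dir, session$subject_id, session$task_label)
  write_dialect(data.frame(time_s = fmt_num(session$time_s),
                           left_cm_s = fmt_num(session$left_velocity),
                           right_cm_s = fmt_num(session$right_velocity)),
                paths$signal)
  write_dialect(data.frame(onset_s = fmt_num(session$events$onset_s),
                           kind = session$events$kind),
                paths$events)
  invisible(paths)
}

#' Read a recording session from CSV
#'
#' Counterpart of [write_session()].
#'
#' @param dir Directory containing the session files.
#' @param subject_id,task_label Identifiers forming the file stem.
#' @param sample_rate_hz Sample rate; inferred from the time column when
#'   `NULL`.
#' @return An `ftcd_session`.
#' @export
read_session <- function(dir, subject_id, task_label, sample_rate_hz = NULL) {
  paths <- session_paths(dir, subject_id, task_label)
  sig <- read_dialect(paths$signal, c("time_s", "left_cm_s", "right_cm_s"))
  ev <- read_dialect(paths$events, c("onset_s", "kind"))
  fs <- sample_rate_hz %||% (1 / stats::median(diff(sig$time_s)))
  sess <- new_session(subject_id, task_label, fs, sig$time_s,
                      sig$left_cm_s, sig$right_cm_s,
                      data.frame(onset_s = ev$onset_s, kind = ev$kind,
                                 stringsAsFactors = FALSE))
  validate_session(sess)
  sess
}

#' List the sessions available in a signals directory
#'
#' @param dir Directory containing `*_signal.csv` / `*_events.csv` pairs.
#' @return Data frame with `subject_id` and `task_label` per session.
#' @export
list_sessions <- function(dir) {
  sig <- list.files(dir, pattern = "_signal\\.csv$")
  stems <- sub("_signal\\.csv$", "", sig)
  parts <- regmatches(stems, regexpr("_[^_]+$", stems))
  data.frame(subject_id = sub("_[^_]+$", "", stems),
             task_label = sub("^_", "", parts),
             stringsAsFactors = FALSE)
}

#' Write / read simulation ground truth
#'
#' `truth.csv` has columns `subject_id`, `task_label`, `true_delta_v_pct`,
#' `latent_trait`.
#'
#' @param truth Ground-truth data frame from [simulate_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, the path (writer) or the data frame (reader).
#' @export
write_truth <- function(truth, path) {
  write_dialect(data.frame(subject_id = truth$subject_id,
                           task_label = truth$task_label,
                           true_delta_v_pct = fmt_num(truth$true_delta_v_pct),
                           latent_trait = fmt_num(truth$latent_trait)),
                path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read_dialect(path, c("subject_id", "task_label", "true_delta_v_pct",
                       "latent_trait"))
}

#' Write / read a subject-task response trace
#'
#' `response_<subject>_<task>.csv` has columns `time_s`,
#' `mean_dv_left_pct`, `mean_dv_right_pct`.
#'
#' @param response An `ftcd_response`.
#' @param dir Output directory.
#' @return Invisibly, the file path (writer); an `ftcd_response` (reader).
#' @export
write_response <- function(response, dir) {
  stopifnot(inherits(response, "ftcd_response"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("response_%s_%s.csv", response$subject_id,
                                 response$task_label))
  write_dialect(data.frame(time_s = fmt_num(response$time_axis_s),
                           mean_dv_left_pct = fmt_num(response$mean_dv_left_pct),
                           mean_dv_right_pct = fmt_num(response$mean_dv_right_pct)),
                path)
  invisible(path)
}

#' @rdname write_response
#' @param path Response CSV path.
#' @param subject_id,task_label Identifiers (parsed from the file name when
#'   `NULL`).
#' @export
read_response <- function(path, subject_id = NULL, task_label = NULL) {
  df <- read_dialect(path, c("time_s", "mean_dv_left_pct",
                             "mean_dv_right_pct"))
  stem <- sub("\\.csv$", "", basename(path))
  bits <- strsplit(sub("^response_", "", stem), "_")[[1]]
  structure(list(time_axis_s = df$time_s,
                 mean_dv_left_pct = df$mean_dv_left_pct,
                 mean_dv_right_pct = df$mean_dv_right_pct,
                 n_good_epochs = NA_integer_,
                 subject_id = subject_id %||% bits[1],
                 task_label = task_label %||% bits[length(bits)],
                 sample_rate_hz = 1 / stats::median(diff(df$time_s))),
            class = "ftcd_response")
}

#' Write the subject QC report
#'
#' `qc_report.csv` has columns `subject_id`, `task_label`, `n_total`,
#' `n_good`, `kept`.
#'
#' @param report Data frame with those columns.
#' @param path Output CSV path.
#' @export
write_qc_report <- function(report, path) {
  write_dialect(report[, c("subject_id", "task_label", "n_total", "n_good",
                           "kept")], path)
  invisible(path)
}

#' Write per-subject lateralization indices
#'
#' `li_results.csv` has columns `subject_id`, `task_label`, `li_pct`,
#' `t_max_s`, `win_lo_s`, `win_hi_s`.
#'
#' @param li_list List of `ftcd_li` objects.
#' @param path Output CSV path.
#' @export
write_li_results <- function(li_list, path) {
  rows <- lapply(li_list, function(li) {
    data.frame(subject_id = li$subject_id, task_label = li$task_label,
               li_pct = fmt_num(li$li_pct), t_max_s = fmt_num(li$t_max_s),
               win_lo_s = fmt_num(li$window_s[1]),
               win_hi_s = fmt_num(li$window_s[2]),
               stringsAsFactors = FALSE)
  })
  write_dialect(do.call(rbind, rows), path)
  invisible(path)
}

#' @rdname write_li_results
#' @export
read_li_results <- function(path) {
  read_dialect(path, c("subject_id", "task_label", "li_pct", "t_max_s",
                       "win_lo_s", "win_hi_s"))
}

#' Write a group trace
#'
#' `group_trace_<task>.csv` has columns `time_s`, `mean_dv`, `sem`.
#'
#' @param gt An `ftcd_group_trace`.
#' @param dir Output directory.
#' @export
write_group_trace <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("group_trace_%s.csv", gt$task_label))
  write_dialect(data.frame(time_s = fmt_num(gt$time_axis_s),
                           mean_dv = fmt_num(gt$mean_delta_v_pct),
                           sem = fmt_num(gt$sem_delta_v_pct)),
                path)
  invisible(path)
}

#' Write the moving-window correlation series
#'
#' `window_correlation.csv` has columns `start_s`, `r`, `p`, `r_critical`,
#' `n`.
#'
#' @param wc An `ftcd_wincor`.
#' @param path Output CSV path.
#' @export
write_window_correlation <- function(wc, path) {
  write_dialect(data.frame(start_s = fmt_num(wc$series$start_s),
                           r = fmt_num(wc$series$r),
                           p = fmt_num(wc$series$p),
                           r_critical = fmt_num(wc$r_critical),
                           n = wc$n_subjects),
                path)
  invisible(path)
}
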