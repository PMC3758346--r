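# End-to-end pipeline: simulate -> preprocess -> lateralize -> correlate,
# with a JSON run manifest recording inputs, outputs and QC exclusions.

#' Read a simulation/pipeline configuration file
#'
#' A flat YAML `key: value` file mirroring the arguments of
#' [ftcd_config()]; unknown keys are rejected. Two-element ranges are
#' YAML lists, per-task effects are maps keyed by task label.
#'
#' @param path Path to the YAML file.
#' @return An `ftcd_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(ftcd_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(ftcd_config, raw)
}

#' Write a configuration to YAML
#'
#' @param config An `ftcd_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

preprocess_stage <- function(signals_dir, out_dir, cutoff_hz = 1, order = 2,
                             threshold_pct = 30, min_good_frac = 0.8) {
  sessions <- list_sessions(signals_dir)
  if (nrow(sessions) == 0) {
    stop(sprintf("no sessions found in %s", signals_dir), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  epoch_sets <- list()
  responses <- list()
  for (i in seq_len(nrow(sessions))) {
    sid <- sessions$subject_id[i]
    task <- sessions$task_label[i]
    sess <- read_session(signals_dir, sid, task)
    pp <- preprocess_session(sess, cutoff_hz = cutoff_hz, order = order,
                             threshold_pct = threshold_pct)
    epoch_sets[[paste(sid, task, sep = "_")]] <- pp$epochs
    responses[[paste(sid, task, sep = "_")]] <- pp$response
  }

  subjects <- unique(sessions$subject_id)
  qc_rows <- list()
  kept_subjects <- character(0)
  for (sid in subjects) {
    tasks <- sessions$task_label[sessions$subject_id == sid]
    sets <- epoch_sets[paste(sid, tasks, sep = "_")]
    names(sets) <- tasks
    qc <- qc_subject(sets, min_good_frac = min_good_frac)
    for (task in tasks) {
      es <- sets[[task]]
      qc_rows[[paste(sid, task)]] <- data.frame(
        subject_id = sid, task_label = task, n_total = es$n_total,
        n_good = es$n_good, kept = qc$keep, stringsAsFactors = FALSE)
    }
    if (qc$keep) {
      kept_subjects <- c(kept_subjects, sid)
      for (task in tasks) {
        write_response(responses[[paste(sid, task, sep = "_")]], out_dir)
      }
    }
  }
  qc_report <- do.call(rbind, qc_rows)
  rownames(qc_report) <- NULL
  write_qc_report(qc_report, file.path(out_dir, "qc_report.csv"))
  list(qc_report = qc_report, kept_subjects = kept_subjects,
       responses = responses)
}

li_stage <- function(responses_dir, out_path, activation_window_s = c(2, 18),
                     t_int_s = 2) {
  files <- list.files(responses_dir, pattern = "^response_.*\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) {
    stop(sprintf("no response files found in %s", responses_dir),
         call. = FALSE)
  }
  lis <- lapply(files, function(f) {
    lateralization_index(delta_v(read_response(f)),
                         activation_window_s = activation_window_s,
                         t_int_s = t_int_s)
  })
  write_li_results(lis, out_path)
  lis
}

correlate_stage <- function(li_path, responses_dir, out_dir, length_s = 5,
                            start_s = -5, stop_s = 15, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  li <- read_li_results(li_path)
  files <- list.files(responses_dir, pattern = "^response_.*\\.csv$",
                      full.names = TRUE)
  traces <- lapply(files, function(f) delta_v(read_response(f)))
  tasks <- sort(unique(vapply(traces, function(tr) tr$task_label,
                              character(1))))
  if (length(tasks) != 2) {
    stop("correlation stage needs responses from exactly two tasks",
         call. = FALSE)
  }
  by_task <- lapply(tasks, function(task) {
    sel <- Filter(function(tr) tr$task_label == task, traces)
    names(sel) <- vapply(sel, function(tr) tr$subject_id, character(1))
    sel
  })
  names(by_task) <- tasks

  for (task in tasks) {
    write_group_trace(group_trace(by_task[[task]]), out_dir)
  }

  step <- 1 / by_task[[1]][[1]]$sample_rate_hz
  wc <- moving_window_correlation(by_task[[1]], by_task[[2]],
                                  starts_s = seq(start_s, stop_s, by = step),
                                  length_s = length_s, alpha = alpha)
  write_window_correlation(wc, file.path(out_dir, "window_correlation.csv"))

  li_a <- li[li$task_label == tasks[1], ]
  li_b <- li[li$task_label == tasks[2], ]
  li_b <- li_b[match(li_a$subject_id, li_b$subject_id), ]
  lc <- li_correlation(li_a$li_pct, li_b$li_pct)
  jsonlite::write_json(lc, file.path(out_dir, "li_correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  list(window_correlation = wc, li_correlation = lc, tasks = tasks)
}

count_rows <- function(path) {
  length(readLines(path, warn = FALSE)) - 1L
}

#' Run the full pipeline on one simulated cohort
#'
#' Executes simulate -> preprocess -> lateralize -> correlate (and
#' optionally report figures) in order, writing every artifact under
#' `out_dir` and a JSON run manifest (`manifest.json`) listing the config
#' snapshot, seed, per-stage outputs with row counts, and QC exclusions.
#' Identical configs (including seed) give byte-identical CSV outputs.
#'
#' @param config An `ftcd_config`, or the path to a YAML config file.
#' @param out_dir Output directory.
#' @param cutoff_hz,order Filter settings.
#' @param threshold_pct Artifact rejection threshold (percent).
#' @param min_good_frac QC retention threshold.
#' @param activation_window_s,t_int_s LI settings.
#' @param make_plots If `TRUE`, render group-trace and correlation figures
#'   as PNG under `out_dir/figures`.
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, out_dir, cutoff_hz = 1, order = 2,
                         threshold_pct = 30, min_good_frac = 0.8,
                         activation_window_s = c(2, 18), t_int_s = 2,
                         make_plots = FALSE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  signals_dir <- file.path(out_dir, "signals")
  responses_dir <- file.path(out_dir, "responses")
  group_dir <- file.path(out_dir, "group")

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  message("stage simulate: ", config$n_subjects, " subjects x 2 tasks")
  cohort <- run_stage("simulate", {
    co <- simulate_cohort(config)
    for (sess in co$sessions) write_session(sess, signals_dir)
    write_truth(co$truth, file.path(signals_dir, "truth.csv"))
    co
  })

  message("stage preprocess")
  pp <- run_stage("preprocess", preprocess_stage(
    signals_dir, responses_dir, cutoff_hz = cutoff_hz, order = order,
    threshold_pct = threshold_pct, min_good_frac = min_good_frac))

  message("stage li")
  li_path <- file.path(out_dir, "li_results.csv")
  run_stage("li", li_stage(responses_dir, li_path,
                           activation_window_s = activation_window_s,
                           t_int_s = t_int_s))

  message("stage correlate")
  corr <- run_stage("correlate", correlate_stage(li_path, responses_dir,
                                                 group_dir))

  if (make_plots) {
    message("stage report")
    run_stage("report", report_stage(out_dir))
  }

  outputs <- c(
    list.files(signals_dir, full.names = TRUE),
    list.files(responses_dir, full.names = TRUE),
    li_path,
    list.files(group_dir, pattern = "\\.csv$", full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ftcdlat")),
    seed = config$seed,
    config = unclass(config),
    n_sessions = length(cohort$sessions),
    kept_subjects = pp$kept_subjects,
    excluded_subjects = setdiff(unique(pp$qc_report$subject_id),
                                pp$kept_subjects),
    qc = pp$qc_report,
    li_correlation = corr$li_correlation,
    outputs = data.frame(path = outputs,
                         rows = vapply(outputs, count_rows, integer(1)),
                         row.names = NULL, stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Verify a run manifest against the files on disk
#'
#' Checks that every output file listed in a manifest exists and that its
#' row count matches on re-read.
#'
#' @param manifest_path Path to `manifest.json`.
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
verify_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (i in seq_len(nrow(man$outputs))) {
    path <- man$outputs$path[i]
    if (!file.exists(path)) {
      stop(sprintf("manifest lists missing file: %s", path), call. = FALSE)
    }
    if (count_rows(path) != man$outputs$rows[i]) {
      stop(sprintf("row count mismatch for %s", path), call. = FALSE)
    }
  }
  invisible(TRUE)
}
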