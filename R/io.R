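## Plain-text readers and writers for every stream. Numeric columns are
## serialized with 17 significant digits so that write -> read round-trips
## are lossless.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

write_text_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- fmt_num(out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a stimulus schedule as CSV
#'
#' Columns: `trial_index`, `trial_type`, `onset_s`, `duration_s`.
#'
#' @param schedule A `stimulus_schedule`.
#' @param path File path.
#' @return `write_schedule_csv` returns `path` invisibly;
#'   `read_schedule_csv` returns a `stimulus_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  write_text_table(as.data.frame(schedule), path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trial_index = "integer",
                                       trial_type = "character",
                                       onset_s = "numeric",
                                       duration_s = "numeric"))
  new_stimulus_schedule(df)
}

#' Write / read a behavior event log as CSV
#'
#' Columns: `time_s`, `event`, `detail`.
#'
#' @param session A [behavior_session()].
#' @param path File path.
#' @return The path (write) or a `behavior_session` (read).
#' @export
write_events_csv <- function(session, path) {
  stopifnot(inherits(session, "behavior_session"))
  write_text_table(as.data.frame(session), path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  behavior_session(utils::read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = c(time_s = "numeric",
                                                  event = "character",
                                                  detail = "character")))
}

#' Write / read an activity series as CSV
#'
#' Columns: `bin_start_s`, `activity_index`, `phase`; the bin width is stored
#' in a `# bin_width_s:` header comment.
#'
#' @param series An [activity_series()].
#' @param path File path.
#' @return The path (write) or an `activity_series` (read).
#' @export
write_activity_csv <- function(series, path) {
  stopifnot(inherits(series, "activity_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_s: %s",
                     fmt_num(attr(series, "bin_width_s"))), con)
  df <- data.frame(bin_start_s = fmt_num(series$start_s),
                   activity_index = fmt_num(series$activity_index),
                   phase = series$phase)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(path) {
  first <- readLines(path, n = 1)
  bw <- as.numeric(sub("# bin_width_s: ", "", first, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  activity_series(data.frame(start_s = df$bin_start_s,
                             activity_index = df$activity_index,
                             phase = df$phase),
                  bin_width_s = bw)
}

#' Write / read fluorescence traces as CSV
#'
#' One row per ROI, one column per frame, with a leading `roi` index column;
#' the frame rate is stored in a `# frame_rate:` header comment. The matching
#' neuropil matrix, when present, goes to a second file.
#'
#' @param recording An [axon_recording()].
#' @param path Fluorescence file path.
#' @param neuropil_path Optional neuropil file path.
#' @param schedule_path Optional schedule CSV path (written via
#'   [write_schedule_csv()]).
#' @return The path (write) or an `axon_recording` (read; pass the same
#'   `neuropil_path`/`schedule_path`).
#' @export
write_traces_csv <- function(recording, path, neuropil_path = NULL,
                             schedule_path = NULL) {
  stopifnot(inherits(recording, "axon_recording"))
  write_mat <- function(m, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("# frame_rate: %s", fmt_num(recording$frame_rate)), con)
    df <- as.data.frame(matrix(fmt_num(m), nrow = nrow(m)))
    names(df) <- paste0("f", seq_len(ncol(m)))
    df <- cbind(roi = seq_len(nrow(m)), df)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  write_mat(recording$fluorescence, path)
  if (!is.null(neuropil_path) && !is.null(recording$neuropil)) {
    write_mat(recording$neuropil, neuropil_path)
  }
  if (!is.null(schedule_path)) {
    write_schedule_csv(recording$schedule, schedule_path)
  }
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path, neuropil_path = NULL,
                            schedule_path = NULL) {
  read_mat <- function(p) {
    fr <- as.numeric(sub("# frame_rate: ", "", readLines(p, n = 1),
                         fixed = TRUE))
    df <- utils::read.csv(p, comment.char = "#")
    list(rate = fr, m = as.matrix(df[, -1, drop = FALSE]))
  }
  fl <- read_mat(path)
  neu <- if (!is.null(neuropil_path)) read_mat(neuropil_path)$m else NULL
  dimnames(fl$m) <- NULL
  if (!is.null(neu)) dimnames(neu) <- NULL
  sched <- if (!is.null(schedule_path)) {
    read_schedule_csv(schedule_path)
  } else {
    new_stimulus_schedule(data.frame(trial_index = integer(0),
                                     trial_type = character(0),
                                     onset_s = numeric(0),
                                     duration_s = numeric(0)))
  }
  axon_recording(fl$m, neuropil = neu, frame_rate = fl$rate, schedule = sched)
}

#' Write a JSON report
#'
#' Thin wrapper over [jsonlite::write_json()] with scalar auto-unboxing,
#' full-precision numbers and stable pretty formatting, so identical inputs
#' produce byte-identical report files.
#'
#' @param report A named list.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
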