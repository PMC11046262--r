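# On-disk table formats. All tables are plain CSV with headers; scalar
# reports are JSON. Timestamps are serialized in seconds at full double
# precision.

detection_log_cols <- c("session_id", "camera_id", "frame_index",
                        "timestamp_s", "detected", "marker_id",
                        paste0("c", rep(0:3, each = 2), c("x", "y")))

#' Empty detection log
#'
#' A detection log has one row per (frame, camera, detection): session and
#' camera identifiers, frame index, timestamp in seconds, a 0/1 `detected`
#' flag, the decoded marker id, and the eight corner coordinates
#' `c0x,c0y,...,c3y` (NA when `detected = 0`).
#'
#' @return Zero-row detection-log data frame.
#' @export
empty_detection_log <- function() {
  df <- data.frame(session_id = character(), camera_id = character(),
                   frame_index = integer(), timestamp_s = numeric(),
                   detected = integer(), marker_id = integer())
  for (cc in detection_log_cols[7:14]) df[[cc]] <- numeric()
  df
}

detection_log_row <- function(session_id, camera_id, frame_index, timestamp_s,
                              marker_id = NA_integer_, corners = NULL) {
  row <- data.frame(session_id = session_id, camera_id = camera_id,
                    frame_index = as.integer(frame_index),
                    timestamp_s = as.numeric(timestamp_s),
                    detected = as.integer(!is.null(corners)),
                    marker_id = as.integer(marker_id))
  cc <- if (is.null(corners)) rep(NA_real_, 8) else as.numeric(t(corners))
  for (i in 1:8) row[[detection_log_cols[6 + i]]] <- cc[i]
  row
}

#' Convert a detection-log row to a marker observation
#'
#' @param row One detected row of a detection log.
#' @return A [marker_observation()].
#' @export
log_row_to_observation <- function(row) {
  stopifnot(nrow(row) == 1, row$detected == 1)
  corners <- matrix(as.numeric(row[1, detection_log_cols[7:14]]), 4, 2,
                    byrow = TRUE)
  marker_observation(row$camera_id, row$frame_index, row$timestamp_s,
                     row$marker_id, corners)
}

#' Read/write detection logs
#'
#' @param log Detection-log data frame.
#' @param path CSV path.
#' @return `read_detection_log` returns the data frame;
#'   `write_detection_log` returns `path` invisibly.
#' @export
write_detection_log <- function(log, path) {
  utils::write.csv(log[, detection_log_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_log
#' @export
read_detection_log <- function(path) {
  df <- utils::read.csv(path, colClasses = c(session_id = "character",
                                             camera_id = "character"))
  missing <- setdiff(detection_log_cols, names(df))
  if (length(missing) > 0) {
    stop("detection log missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read/write trial-event logs
#'
#' Trial-event tables have columns `trial_index`, `kind` (`active` or
#' `inter_trial`), `start_s`, `end_s`, `trial_type` (`go`, `no_go`, `n/a`).
#'
#' @param windows Trial-window data frame.
#' @param path CSV path.
#' @export
write_trial_events <- function(windows, path) {
  utils::write.csv(windows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_events
#' @export
read_trial_events <- function(path) {
  df <- utils::read.csv(path, colClasses = c(kind = "character",
                                             trial_type = "character"))
  validate_trial_windows(df)
  df
}

#' Read/write trial scores
#'
#' Trial-score tables have columns `trial_index`, `label`, `n_frames_seen`,
#' `n_frames_engaged`, `first_engaged_s`.
#'
#' @param scores Trial-score data frame from [score_session()].
#' @param path CSV path.
#' @export
write_trial_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_scores
#' @export
read_trial_scores <- function(path) {
  utils::read.csv(path, colClasses = c(label = "character"))
}

#' Read/write engagement traces
#'
#' Trace tables have columns `eval_min`, `n_trials`, `prob_pct`, `defined`,
#' `truncated`.
#'
#' @param trace Trace data frame from [engagement_trace()].
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.csv(path)
}
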