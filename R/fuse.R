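# Multi-camera stream fusion.
#
# Real capture clocks drift, so frames are paired across cameras by nearest
# timestamp within half a frame period rather than by index. Fusion is a
# logical OR of detections: a paired frame time counts as detected when any
# camera saw the marker at that time.

#' Frame account
#'
#' Tallies per-frame detection coverage over paired frame times for a
#' two-camera setup: frames seen by camera 1 exclusively, camera 2
#' exclusively, both, or neither. The four categories always partition the
#' total.
#'
#' @param n_cam1_only,n_cam2_only,n_both,n_neither Non-negative counts.
#' @return Object of class `frame_account` with an `n_total_frames` field.
#' @export
frame_account <- function(n_cam1_only, n_cam2_only, n_both, n_neither) {
  counts <- c(n_cam1_only, n_cam2_only, n_both, n_neither)
  if (any(counts < 0)) stop("frame counts must be non-negative", call. = FALSE)
  structure(list(n_total_frames = sum(counts),
                 n_cam1_only = n_cam1_only, n_cam2_only = n_cam2_only,
                 n_both = n_both, n_neither = n_neither),
            class = "frame_account")
}

#' @export
print.frame_account <- function(x, ...) {
  pct <- function(n) sprintf("%d (%.1f%%)", n, 100 * n / max(1, x$n_total_frames))
  cat("Frame account over", x$n_total_frames, "paired frames\n")
  cat("  camera 1 only:", pct(x$n_cam1_only), "\n")
  cat("  camera 2 only:", pct(x$n_cam2_only), "\n")
  cat("  both cameras: ", pct(x$n_both), "\n")
  cat("  neither:      ", pct(x$n_neither), "\n")
  invisible(x)
}

#' Fuse per-camera detection streams
#'
#' Pairs frames across camera streams by timestamp (greedy clustering within
#' half a frame period) and combines detections by logical OR. Frames that
#' cannot be paired (clock drift beyond tolerance) stay in the fused
#' sequence as single-camera frame times, with a warning.
#'
#' @param streams List of per-camera detection-log data frames (see
#'   [empty_detection_log()]); names are camera ids (taken from the logs
#'   when unnamed).
#' @param frame_period Seconds between frames; estimated from median
#'   timestamp spacing when `NULL`.
#' @return List with `frames` (the input rows plus a `paired_frame` id and
#'   shared `paired_time`), `coverage` (fraction of paired frame times with
#'   at least one detection), `per_camera_coverage`, and `account` (a
#'   [frame_account()]; `NULL` unless exactly two cameras).
#' @export
fuse_streams <- function(streams, frame_period = NULL) {
  if (length(streams) == 0) stop("no camera streams supplied", call. = FALSE)
  cams <- names(streams)
  if (is.null(cams)) {
    cams <- vapply(streams, function(s) s$camera_id[1], character(1))
    names(streams) <- cams
  }
  all_rows <- do.call(rbind, streams)
  if (is.null(frame_period)) {
    dts <- unlist(lapply(streams, function(s) diff(sort(unique(s$timestamp_s)))))
    frame_period <- if (length(dts) > 0) stats::median(dts) else 1
  }
  tol <- frame_period / 2
  ord <- order(all_rows$timestamp_s, all_rows$camera_id, all_rows$frame_index)
  all_rows <- all_rows[ord, , drop = FALSE]
  # greedy clustering: a new paired frame starts when the time gap exceeds
  # tol or the camera already contributed to the open cluster
  n <- nrow(all_rows)
  cluster <- integer(n)
  cur <- 0; t0 <- -Inf; seen <- character(0)
  for (i in seq_len(n)) {
    ti <- all_rows$timestamp_s[i]; ci <- all_rows$camera_id[i]
    same_frame <- i > 1 && cluster[i - 1] == cur &&
      all_rows$frame_index[i] == all_rows$frame_index[i - 1] &&
      ci == all_rows$camera_id[i - 1]   # multi-detection rows of one frame
    if (!same_frame && (ti - t0 > tol || ci %in% seen)) {
      cur <- cur + 1; t0 <- ti; seen <- character(0)
    }
    if (!(ci %in% seen)) seen <- c(seen, ci)
    cluster[i] <- cur
  }
  all_rows$paired_frame <- cluster
  all_rows$paired_time <- stats::ave(all_rows$timestamp_s, cluster)
  # drift diagnostics: clusters missing a camera that has frames nearby
  n_frames <- max(cluster)
  det_by <- lapply(streams, function(s) {
    f <- all_rows$camera_id == s$camera_id[1] & all_rows$detected == 1
    unique(all_rows$paired_frame[f])
  })
  names(det_by) <- cams
  present_by <- lapply(cams, function(cm)
    unique(all_rows$paired_frame[all_rows$camera_id == cm]))
  names(present_by) <- cams
  if (length(cams) > 1) {
    unpaired <- n_frames - length(Reduce(intersect, present_by))
    if (unpaired > 0) {
      warning(unpaired, " frame time(s) could not be paired across all cameras",
              call. = FALSE)
    }
  }
  fused_detected <- sort(unique(unlist(det_by)))
  per_cov <- vapply(det_by, function(d) length(d) / n_frames, numeric(1))
  account <- NULL
  if (length(cams) == 2) {
    in1 <- seq_len(n_frames) %in% det_by[[1]]
    in2 <- seq_len(n_frames) %in% det_by[[2]]
    account <- frame_account(sum(in1 & !in2), sum(!in1 & in2),
                             sum(in1 & in2), sum(!in1 & !in2))
  }
  list(frames = all_rows,
       n_paired_frames = n_frames,
       coverage = length(fused_detected) / n_frames,
       per_camera_coverage = per_cov,
       account = account)
}
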