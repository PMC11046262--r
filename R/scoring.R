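# Per-frame engagement classification and trial-level scoring.
#
# A frame classifies as engaged when the marker was detected, its center
# lies inside at least one region of interest of the detecting camera, and
# its nose-ward yaw relative to that camera's module wall falls inside the
# closed window [yaw_min, yaw_max]. Undetected frames (occlusion) default to
# distracted. A trial is engaged if ANY of its frames classifies engaged on
# any camera, regardless of interleaved distraction.

#' Classifier configuration
#'
#' Geometry and thresholds for engagement classification: one or more
#' regions of interest and a module-wall segment per camera, the nose-side
#' front edge of the marker, and the engaged yaw window (default 5-175
#' degrees, endpoints inclusive; 90 degrees means facing the wall squarely).
#' The broad window deliberately gives the animal leeway in orientation.
#'
#' @param rois List of [region_of_interest()] objects (any number per
#'   camera).
#' @param walls Named list of [wall_spec()] objects, one per camera id.
#' @param front_edge Marker edge (0..3) closest to the animal's nose.
#' @param yaw_min,yaw_max Engaged yaw window in degrees,
#'   `0 <= yaw_min < yaw_max <= 180`.
#' @param target_marker_id Dictionary id of the tracked marker.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(rois, walls, front_edge = 0,
                              yaw_min = 5, yaw_max = 175,
                              target_marker_id = 0) {
  if (inherits(rois, "region_of_interest")) rois <- list(rois)
  stopifnot(all(vapply(rois, inherits, logical(1), "region_of_interest")))
  if (inherits(walls, "wall_spec")) stop("'walls' must be a named list keyed by camera id", call. = FALSE)
  stopifnot(all(vapply(walls, inherits, logical(1), "wall_spec")))
  if (is.null(names(walls)) || any(names(walls) == "")) {
    stop("'walls' must be named by camera id", call. = FALSE)
  }
  if (!(front_edge %in% 0:3)) stop("'front_edge' must be in 0..3", call. = FALSE)
  if (!(yaw_min >= 0 && yaw_min < yaw_max && yaw_max <= 180)) {
    stop("need 0 <= yaw_min < yaw_max <= 180", call. = FALSE)
  }
  roi_cams <- vapply(rois, function(r) r$camera_id, character(1))
  missing_wall <- setdiff(roi_cams, names(walls))
  if (length(missing_wall) > 0) {
    stop("no wall configured for camera(s): ",
         paste(missing_wall, collapse = ", "), call. = FALSE)
  }
  structure(list(rois = rois, walls = walls, front_edge = front_edge,
                 yaw_min = yaw_min, yaw_max = yaw_max,
                 target_marker_id = as.integer(target_marker_id)),
            class = "classifier_config")
}

cameras_of <- function(cfg) names(cfg$walls)

rois_for_camera <- function(cfg, camera_id) {
  Filter(function(r) r$camera_id == camera_id, cfg$rois)
}

#' Classify a single frame observation
#'
#' @param obs A [marker_observation()] or `NULL`/missing observation
#'   (occlusion), which classifies as distracted.
#' @param cfg A [classifier_config()].
#' @return `"engaged"` or `"distracted"`.
#' @export
classify_frame <- function(obs, cfg) {
  stopifnot(inherits(cfg, "classifier_config"))
  if (is.null(obs)) return("distracted")
  stopifnot(inherits(obs, "marker_observation"))
  cam <- obs$camera_id
  if (!(cam %in% cameras_of(cfg))) {
    stop("no wall/ROI configured for camera ", cam, call. = FALSE)
  }
  rois <- rois_for_camera(cfg, cam)
  if (length(rois) == 0) {
    stop("no region of interest configured for camera ", cam, call. = FALSE)
  }
  pose <- pose_from_corners(obs, cfg$front_edge)
  in_roi <- any(vapply(rois, function(r) point_in_roi(pose$center, r), logical(1)))
  if (!in_roi) return("distracted")
  yaw <- yaw_angle(pose$heading, cfg$walls[[cam]])
  if (yaw >= cfg$yaw_min && yaw <= cfg$yaw_max) "engaged" else "distracted"
}

# Vectorized classification over a detection log: adds an `engaged` 0/1
# column. Internal; exported wrapper below.
classify_log_rows <- function(log, cfg) {
  n <- nrow(log)
  engaged <- integer(n)
  if (n == 0) { log$engaged <- engaged; return(log) }
  det <- which(log$detected == 1 & !is.na(log$marker_id) &
                 log$marker_id == cfg$target_marker_id)
  for (cam in unique(log$camera_id[det])) {
    if (!(cam %in% cameras_of(cfg))) {
      stop("no wall/ROI configured for camera ", cam, call. = FALSE)
    }
    idx <- det[log$camera_id[det] == cam]
    cx <- (log$c0x[idx] + log$c1x[idx] + log$c2x[idx] + log$c3x[idx]) / 4
    cy <- (log$c0y[idx] + log$c1y[idx] + log$c2y[idx] + log$c3y[idx]) / 4
    fe <- cfg$front_edge
    xs <- cbind(log$c0x[idx], log$c1x[idx], log$c2x[idx], log$c3x[idx])
    ys <- cbind(log$c0y[idx], log$c1y[idx], log$c2y[idx], log$c3y[idx])
    i <- fe + 1L; j <- fe %% 4L + 2L; if (j == 5L) j <- 1L
    hx <- (xs[, i] + xs[, j]) / 2 - cx
    hy <- (ys[, i] + ys[, j]) / 2 - cy
    yaw <- yaw_angle(cbind(hx, hy), cfg$walls[[cam]])
    rois <- rois_for_camera(cfg, cam)
    if (length(rois) == 0) {
      stop("no region of interest configured for camera ", cam, call. = FALSE)
    }
    in_roi <- Reduce(`|`, lapply(rois, function(r) point_in_roi(cbind(cx, cy), r)))
    engaged[idx] <- as.integer(in_roi & yaw >= cfg$yaw_min & yaw <= cfg$yaw_max)
  }
  log$engaged <- engaged
  log
}

#' Classify every row of a detection log
#'
#' Applies the frame classifier to each detection-log row, vectorized.
#'
#' @param log Detection-log data frame.
#' @param cfg A [classifier_config()].
#' @return The log with an added `engaged` 0/1 column (0 for undetected
#'   rows).
#' @export
classify_detections <- function(log, cfg) {
  stopifnot(inherits(cfg, "classifier_config"))
  classify_log_rows(log, cfg)
}

#' Trial windows for a session
#'
#' Builds the alternating active/inter-trial timeline: each active trial
#' (default 6 s) is followed by an inter-trial period (default 3 s).
#'
#' @param n_trials Number of active trials.
#' @param active_s,inter_s Durations in seconds.
#' @param trial_type Character vector of trial types (`go`/`no_go`),
#'   recycled; inter-trial rows get `n/a`.
#' @param t0 Session start offset in seconds.
#' @return Data frame with `trial_index`, `kind`, `start_s`, `end_s`,
#'   `trial_type`.
#' @export
trial_windows <- function(n_trials, active_s = 6, inter_s = 3,
                          trial_type = "go", t0 = 0) {
  stopifnot(n_trials >= 1, active_s > 0, inter_s >= 0)
  types <- rep_len(trial_type, n_trials)
  cyc <- active_s + inter_s
  starts <- t0 + (seq_len(n_trials) - 1) * cyc
  active <- data.frame(trial_index = seq_len(n_trials), kind = "active",
                       start_s = starts, end_s = starts + active_s,
                       trial_type = types)
  inter <- data.frame(trial_index = seq_len(n_trials), kind = "inter_trial",
                      start_s = starts + active_s, end_s = starts + cyc,
                      trial_type = "n/a")
  out <- rbind(active, inter)
  out <- out[order(out$start_s, out$kind), ]
  rownames(out) <- NULL
  validate_trial_windows(out)
  out
}

validate_trial_windows <- function(w) {
  need <- c("trial_index", "kind", "start_s", "end_s", "trial_type")
  missing <- setdiff(need, names(w))
  if (length(missing) > 0) {
    stop("trial windows missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(w$end_s <= w$start_s)) stop("trial windows must have end > start", call. = FALSE)
  if (!all(w$kind %in% c("active", "inter_trial"))) {
    stop("window kind must be 'active' or 'inter_trial'", call. = FALSE)
  }
  act <- w[w$kind == "active", ]
  act <- act[order(act$start_s), ]
  if (nrow(act) > 1 && any(act$start_s[-1] < act$end_s[-nrow(act)] - 1e-9)) {
    stop("active trial windows overlap", call. = FALSE)
  }
  invisible(w)
}

#' Score one trial window
#'
#' Any-frame rule: the trial is engaged if at least one frame inside
#' `[start, end)` classifies engaged on any camera; a trial with no frames
#' at all (total occlusion) is distracted.
#'
#' @param frames Data frame with at least `timestamp_s` (or `paired_time`)
#'   and `engaged` columns, e.g. from [classify_detections()].
#' @param window One-row active trial window.
#' @return List of class `trial_score`: `trial_index`, `label`,
#'   `n_frames_seen`, `n_frames_engaged`, `first_engaged_s`.
#' @export
score_trial <- function(frames, window) {
  if (window$end_s <= window$start_s) stop("zero-length trial window", call. = FALSE)
  tcol <- if ("paired_time" %in% names(frames)) "paired_time" else "timestamp_s"
  fcol <- if ("paired_frame" %in% names(frames)) "paired_frame" else "frame_index"
  inw <- frames[[tcol]] >= window$start_s & frames[[tcol]] < window$end_s
  sub <- frames[inw, , drop = FALSE]
  seen <- sub[sub$detected == 1, , drop = FALSE]
  eng <- sub[sub$engaged == 1, , drop = FALSE]
  first_t <- if (nrow(eng) > 0) min(eng[[tcol]]) else NA_real_
  structure(list(trial_index = window$trial_index,
                 label = if (nrow(eng) > 0) "engaged" else "distracted",
                 n_frames_seen = length(unique(seen[[fcol]])),
                 n_frames_engaged = length(unique(eng[[fcol]])),
                 first_engaged_s = first_t),
            class = "trial_score")
}

#' Score a whole session against its trial timeline
#'
#' Classifies every detection (if not already classified) and applies the
#' any-frame rule to each active trial window. Inter-trial frames are
#' classified for annotation but never scored. Frames outside all windows
#' are ignored with a message.
#'
#' @param frames Detection log (single camera or fused `$frames` from
#'   [fuse_streams()]).
#' @param windows Trial-window data frame (see [trial_windows()]).
#' @param cfg A [classifier_config()].
#' @return Data frame with one row per active trial: `trial_index`, `label`,
#'   `n_frames_seen`, `n_frames_engaged`, `first_engaged_s`.
#' @export
score_session <- function(frames, windows, cfg) {
  validate_trial_windows(windows)
  if (!("engaged" %in% names(frames))) frames <- classify_detections(frames, cfg)
  tcol <- if ("paired_time" %in% names(frames)) "paired_time" else "timestamp_s"
  act <- windows[windows$kind == "active", , drop = FALSE]
  act <- act[order(act$start_s), , drop = FALSE]
  covered <- rep(FALSE, nrow(frames))
  for (k in seq_len(nrow(windows))) {
    covered <- covered | (frames[[tcol]] >= windows$start_s[k] &
                            frames[[tcol]] < windows$end_s[k])
  }
  n_out <- sum(!covered)
  if (n_out > 0) {
    message(n_out, " frame row(s) fall outside all trial windows; ignored")
  }
  scores <- lapply(seq_len(nrow(act)), function(k) {
    s <- score_trial(frames, act[k, ])
    data.frame(trial_index = s$trial_index, label = s$label,
               n_frames_seen = s$n_frames_seen,
               n_frames_engaged = s$n_frames_engaged,
               first_engaged_s = s$first_engaged_s)
  })
  out <- do.call(rbind, scores)
  rownames(out) <- NULL
  out
}

#' Annotation color for live display
#'
#' The on-screen marker outline color combines the trial phase with the
#' instantaneous engagement state: green (active, engaged), yellow (active,
#' distracted), purple (inter-trial, engaged), pink (inter-trial,
#' distracted).
#'
#' @param window_kind `"active"` or `"inter_trial"`.
#' @param label `"engaged"` or `"distracted"`.
#' @return One of `"green"`, `"yellow"`, `"purple"`, `"pink"`.
#' @export
annotation_state <- function(window_kind, label) {
  window_kind <- match.arg(window_kind, c("active", "inter_trial"))
  label <- match.arg(label, c("engaged", "distracted"))
  if (window_kind == "active") {
    if (label == "engaged") "green" else "yellow"
  } else {
    if (label == "engaged") "purple" else "pink"
  }
}
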