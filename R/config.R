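# Session configuration: YAML schema, validation, and save/load round-trip.
#
# A session config ties together camera frame sources, per-camera classifier
# geometry, trial timing defaults, and dynamics parameters. Validation
# collects every offending field before failing, so a bad file is reported
# in one pass.

#' Load a session configuration
#'
#' Reads and validates a YAML session configuration. Omitted fields take
#' the package defaults (yaw window 5-175 degrees, 6 s active / 3 s
#' inter-trial, 5 min kernel / 1 min step / 50% threshold, 60 fps). A
#' schema violation raises an error listing every offending field.
#'
#' The schema (top level): `session_id`, `seed`, `fps`, `output_dir`,
#' `log_level`, `cameras` (list of `{id, frames_dir}`), `classifier`
#' (`front_edge`, `yaw_min`, `yaw_max`, `target_marker_id`, `per_camera`:
#' map of camera id to `{rois: list of vertex lists, wall: {p0, p1,
#' interior_hint}}`), `trial` (`active_s`, `inter_s`), `dynamics`
#' (`window_min`, `step_min`, `threshold_pct`).
#'
#' @param path YAML file path, or an already-parsed list.
#' @return Object of class `session_config` with elements `session_id`,
#'   `seed`, `fps`, `cameras`, `classifier` (a [classifier_config()]),
#'   `trial`, `dynamics` (a [dynamics_config()]), `output_dir`,
#'   `log_level`.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  session_id <- raw$session_id %||% "session"
  seed <- raw$seed %||% 1L
  fps <- raw$fps %||% 60
  if (!is.numeric(fps) || fps <= 0) note("fps: must be a positive number")
  output_dir <- raw$output_dir %||% "."
  log_level <- raw$log_level %||% "info"
  if (!log_level %in% c("debug", "info", "warning", "error")) {
    note("log_level: must be one of debug/info/warning/error")
  }

  cams <- raw$cameras
  if (is.null(cams) || length(cams) == 0) {
    note("cameras: at least one camera required")
    cams <- list()
  }
  cam_ids <- vapply(cams, function(cm) as.character(cm$id %||% NA_character_),
                    character(1))
  if (any(is.na(cam_ids))) note("cameras: every camera needs an id")
  if (anyDuplicated(cam_ids[!is.na(cam_ids)])) note("cameras: duplicate camera ids")

  cl <- raw$classifier %||% list()
  front_edge <- cl$front_edge %||% 0
  yaw_min <- cl$yaw_min %||% 5
  yaw_max <- cl$yaw_max %||% 175
  target_marker_id <- cl$target_marker_id %||% 0
  if (!front_edge %in% 0:3) note("classifier.front_edge: must be in 0..3")
  if (!is.numeric(yaw_min) || !is.numeric(yaw_max) ||
      !(yaw_min >= 0 && yaw_min < yaw_max && yaw_max <= 180)) {
    note("classifier.yaw_min/yaw_max: need 0 <= yaw_min < yaw_max <= 180")
  }

  rois <- list(); walls <- list()
  for (id in cam_ids[!is.na(cam_ids)]) {
    pc <- cl$per_camera[[id]]
    if (is.null(pc)) {
      note(sprintf("classifier.per_camera.%s: missing geometry", id))
      next
    }
    if (is.null(pc$rois) || length(pc$rois) == 0) {
      note(sprintf("classifier.per_camera.%s.rois: at least one ROI required", id))
    } else {
      for (vr in pc$rois) {
        v <- do.call(rbind, lapply(vr, as.numeric))
        if (ncol(v) != 2 || nrow(v) < 3) {
          note(sprintf("classifier.per_camera.%s.rois: polygons need >= 3 (x, y) vertices", id))
        } else {
          rois[[length(rois) + 1]] <- region_of_interest(id, v)
        }
      }
    }
    wl <- pc$wall
    if (is.null(wl$p0) || is.null(wl$p1) || is.null(wl$interior_hint)) {
      note(sprintf("classifier.per_camera.%s.wall: needs p0, p1, interior_hint", id))
    } else {
      ws <- try(wall_spec(as.numeric(wl$p0), as.numeric(wl$p1),
                          as.numeric(wl$interior_hint)), silent = TRUE)
      if (inherits(ws, "try-error")) {
        note(sprintf("classifier.per_camera.%s.wall: %s", id,
                     attr(ws, "condition")$message))
      } else {
        walls[[id]] <- ws
      }
    }
  }

  tr <- raw$trial %||% list()
  active_s <- tr$active_s %||% 6
  inter_s <- tr$inter_s %||% 3
  if (!is.numeric(active_s) || active_s <= 0) note("trial.active_s: must be positive")
  if (!is.numeric(inter_s) || inter_s < 0) note("trial.inter_s: must be non-negative")

  dy <- raw$dynamics %||% list()
  window_min <- dy$window_min %||% 5
  step_min <- dy$step_min %||% 1
  threshold_pct <- dy$threshold_pct %||% 50
  if (!is.numeric(window_min) || window_min <= 0) note("dynamics.window_min: must be positive")
  if (!is.numeric(step_min) || step_min <= 0) note("dynamics.step_min: must be positive")
  if (!is.numeric(threshold_pct) || threshold_pct <= 0 || threshold_pct >= 100) {
    note("dynamics.threshold_pct: must be in (0, 100)")
  }

  if (length(errs) > 0) {
    stop("invalid session configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }

  classifier <- classifier_config(rois, walls, front_edge = front_edge,
                                  yaw_min = yaw_min, yaw_max = yaw_max,
                                  target_marker_id = target_marker_id)
  cameras <- lapply(seq_along(cams), function(i)
    list(id = cam_ids[i], frames_dir = cams[[i]]$frames_dir))
  structure(list(session_id = session_id, seed = as.integer(seed), fps = fps,
                 cameras = cameras, classifier = classifier,
                 trial = list(active_s = active_s, inter_s = inter_s),
                 dynamics = dynamics_config(window_min, step_min, threshold_pct),
                 output_dir = output_dir, log_level = log_level),
            class = "session_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a session configuration
#'
#' Writes a [load_config()]-compatible YAML file; `load_config(save_config(
#' cfg, path))` reproduces the configuration exactly.
#'
#' @param cfg A `session_config`.
#' @param path Output YAML path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "session_config"))
  per_cam <- list()
  for (id in names(cfg$classifier$walls)) {
    rr <- rois_for_camera(cfg$classifier, id)
    w <- cfg$classifier$walls[[id]]
    per_cam[[id]] <- list(
      rois = lapply(rr, function(r) lapply(seq_len(nrow(r$vertices)),
                                           function(i) as.numeric(r$vertices[i, ]))),
      wall = list(p0 = w$p0, p1 = w$p1, interior_hint = w$interior_hint))
  }
  raw <- list(
    session_id = cfg$session_id, seed = cfg$seed, fps = cfg$fps,
    output_dir = cfg$output_dir, log_level = cfg$log_level,
    cameras = lapply(cfg$cameras, function(cm)
      if (is.null(cm$frames_dir)) list(id = cm$id)
      else list(id = cm$id, frames_dir = cm$frames_dir)),
    classifier = list(front_edge = cfg$classifier$front_edge,
                      yaw_min = cfg$classifier$yaw_min,
                      yaw_max = cfg$classifier$yaw_max,
                      target_marker_id = cfg$classifier$target_marker_id,
                      per_camera = per_cam),
    trial = cfg$trial,
    dynamics = list(window_min = cfg$dynamics$window_min,
                    step_min = cfg$dynamics$step_min,
                    threshold_pct = cfg$dynamics$threshold_pct))
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Composes detection (or pre-extracted logs), multi-camera fusion,
#' trial scoring, the engagement-dynamics trace, and - when a manual
#' reference is supplied - validation metrics. All outputs are written to
#' `out_dir` as CSV/JSON and also returned.
#'
#' @param cfg A `session_config` from [load_config()].
#' @param trial_events Trial-event table or CSV path.
#' @param detection_logs Named list of per-camera detection logs (or CSV
#'   paths); when `NULL`, frames are detected from each camera's
#'   `frames_dir`.
#' @param truth Optional manual trial labels: data frame with `trial_index`
#'   and `label`, or a CSV path.
#' @param out_dir Output directory; defaults to the config's `output_dir`.
#' @return List: `scores`, `trace`, `disengagement_min`, `fused`
#'   (`coverage`, `account`), `metrics` (`NULL` without truth), and the
#'   paths written.
#' @export
run_pipeline <- function(cfg, trial_events, detection_logs = NULL,
                         truth = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "session_config"))
  out_dir <- out_dir %||% cfg$output_dir
  if (is.character(trial_events)) {
    if (!file.exists(trial_events)) stop("missing trial-event log: ", trial_events, call. = FALSE)
    trial_events <- read_trial_events(trial_events)
  }
  validate_trial_windows(trial_events)
  if (is.character(truth)) {
    if (!file.exists(truth)) stop("missing truth table: ", truth, call. = FALSE)
    truth <- utils::read.csv(truth, colClasses = c(label = "character"))
  }
  cam_ids <- vapply(cfg$cameras, function(cm) cm$id, character(1))
  if (is.null(detection_logs)) {
    dirs <- lapply(cfg$cameras, function(cm) cm$frames_dir)
    missing <- cam_ids[vapply(dirs, function(d) is.null(d) || !dir.exists(d), logical(1))]
    if (length(missing) > 0) {
      stop("no detection log or frames_dir for camera(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    detection_logs <- lapply(seq_along(cam_ids), function(i)
      detect_frames_dir(dirs[[i]], cam_ids[i], fps = cfg$fps,
                        target_marker_id = cfg$classifier$target_marker_id,
                        session_id = cfg$session_id))
    names(detection_logs) <- cam_ids
  } else {
    detection_logs <- lapply(detection_logs, function(l)
      if (is.character(l)) read_detection_log(l) else l)
    if (is.null(names(detection_logs))) {
      names(detection_logs) <- vapply(detection_logs,
                                      function(l) l$camera_id[1], character(1))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fused <- fuse_streams(detection_logs, frame_period = 1 / cfg$fps)
  frames <- classify_detections(fused$frames, cfg$classifier)
  scores <- score_session(frames, trial_events, cfg$classifier)
  series <- session_series(scores, trial_events)
  trace <- engagement_trace(series, cfg$dynamics,
                            session_end_s = max(trial_events$end_s))
  dis_min <- disengagement_time(trace, cfg$dynamics)

  paths <- list(
    detections = file.path(out_dir, "detections.csv"),
    scores = file.path(out_dir, "trial_scores.csv"),
    trace = file.path(out_dir, "trace.csv"),
    summary = file.path(out_dir, "summary.json"))
  write_detection_log(fused$frames, paths$detections)
  write_trial_scores(scores, paths$scores)
  write_trace(trace, paths$trace)

  metrics <- NULL
  if (!is.null(truth)) {
    joined <- merge(scores[, c("trial_index", "label")], truth,
                    by = "trial_index", suffixes = c("_pred", "_true"))
    cm <- confusion_from_labels(joined$label_pred, joined$label_true)
    metrics <- compute_metrics(cm)
    paths$metrics <- file.path(out_dir, "metrics.json")
    paths$confusion <- file.path(out_dir, "confusion.csv")
    jsonlite::write_json(metrics[c("accuracy", "precision", "sensitivity",
                                   "specificity", "f1", "mcc")],
                         paths$metrics, auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN),
                     paths$confusion, row.names = FALSE)
  }
  summary <- list(session_id = cfg$session_id,
                  n_trials = nrow(scores),
                  n_engaged = sum(scores$label == "engaged"),
                  probability_of_engagement_pct =
                    probability_of_engagement(sum(scores$label == "engaged"),
                                              nrow(scores)),
                  disengagement_min = dis_min,
                  fused_coverage = fused$coverage)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       na = "null")

  list(scores = scores, trace = trace, disengagement_min = dis_min,
       fused = fused[c("coverage", "per_camera_coverage", "account")],
       metrics = metrics, paths = paths)
}
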