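# Ground-truth session simulator.
#
# The generator emulates a two-state (engaged/distracted) latent process at
# per-trial granularity: before the planted disengagement time every trial
# is in the engaged state, after it in the distracted state, and the trial's
# behavioral label is drawn from the state-conditional engagement
# probability. Per-frame marker poses realize the label geometrically
# (engaged poses satisfy the classifier's ROI + yaw gates, distracted poses
# violate one of the two gates, half each), with small within-trial pose
# jitter. Per-camera detection dropout emulates occlusion. Everything is
# deterministic for a fixed seed.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 32 min sessions of 6 s active
#' trials with 3 s inter-trial periods at 60 fps, two cameras with strongly
#' asymmetric occlusion dropout (union coverage about 0.7), and a
#' state-conditional engagement probability of 0.9515 while attentive
#' (matching the observed engaged-trial fraction in standard-length
#' sessions) falling to 0.05 after the planted disengagement time.
#'
#' @param seed Integer RNG seed; every random draw in the simulator flows
#'   from it.
#' @param session_min Session length, minutes.
#' @param trial_active_s,trial_inter_s Active and inter-trial durations, s.
#' @param fps Frame rate of the simulated cameras, Hz.
#' @param n_cameras 1 or 2.
#' @param p_engaged Named vector `c(engaged = , distracted = )`:
#'   probability that a trial in each latent state is behaviorally engaged.
#' @param disengagement_min Planted latent switch time in minutes, or `NULL`
#'   for a session that stays attentive throughout.
#' @param dropout_prob Per-camera probability that a frame's detection is
#'   lost to occlusion (length `n_cameras`).
#' @param marker_size_px Marker side length in pixels (observation geometry
#'   and rendering).
#' @param frame_size `c(width, height)` of the camera frames, pixels.
#' @param generate_frames If `FALSE`, only trial windows and ground-truth
#'   labels are produced (no per-frame streams); used for label-level
#'   analyses where frame geometry is irrelevant.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed, session_min = 32, trial_active_s = 6,
                       trial_inter_s = 3, fps = 60, n_cameras = 2,
                       p_engaged = c(engaged = 0.9515, distracted = 0.05),
                       disengagement_min = NULL,
                       dropout_prob = c(0.80, 0.35),
                       marker_size_px = 40, frame_size = c(320, 240),
                       generate_frames = TRUE) {
  stopifnot(session_min > 0, trial_active_s > 0, trial_inter_s >= 0,
            fps > 0, n_cameras %in% 1:2,
            all(p_engaged >= 0 & p_engaged <= 1),
            all(c("engaged", "distracted") %in% names(p_engaged)),
            all(dropout_prob >= 0 & dropout_prob <= 1),
            marker_size_px > 0, length(frame_size) == 2)
  if (!is.null(disengagement_min)) stopifnot(disengagement_min > 0)
  structure(list(seed = as.integer(seed), session_min = session_min,
                 trial_active_s = trial_active_s, trial_inter_s = trial_inter_s,
                 fps = fps, n_cameras = as.integer(n_cameras),
                 p_engaged = p_engaged,
                 disengagement_min = disengagement_min,
                 dropout_prob = rep_len(dropout_prob, n_cameras),
                 marker_size_px = marker_size_px,
                 frame_size = frame_size,
                 generate_frames = isTRUE(generate_frames)),
            class = "sim_config")
}

#' Default classifier geometry for the simulated chamber
#'
#' A standard synthetic chamber seen from above: the module wall is the
#' right frame edge, the region of interest spans from the chamber midline
#' to that wall, and the interior hint is the frame center. The same
#' geometry is used for every camera.
#'
#' @param frame_size `c(width, height)`, pixels.
#' @param cameras Character vector of camera ids.
#' @param ... Passed to [classifier_config()] (e.g. `yaw_min`,
#'   `target_marker_id`).
#' @return A [classifier_config()].
#' @export
default_classifier_config <- function(frame_size = c(320, 240),
                                      cameras = c("cam1", "cam2"), ...) {
  w <- frame_size[1]; h <- frame_size[2]
  rois <- lapply(cameras, function(cm)
    region_of_interest(cm, rbind(c(w / 2, 0), c(w, 0), c(w, h), c(w / 2, h))))
  walls <- stats::setNames(
    lapply(cameras, function(cm)
      wall_spec(c(w, 0), c(w, h), interior_hint = c(w / 2, h / 2))),
    cameras)
  classifier_config(rois = rois, walls = walls, ...)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# heading vector for a yaw angle (degrees) in a wall's (direction, normal)
# frame
heading_from_yaw <- function(yaw_deg, wall) {
  w <- wall$p1 - wall$p0
  w <- w / sqrt(sum(w^2))
  n <- c(w[2], -w[1])
  if (sum((wall$p0 - wall$interior_hint) * n) < 0) n <- -n
  th <- yaw_deg * pi / 180
  cbind(cos(th) * w[1] + sin(th) * n[1], cos(th) * w[2] + sin(th) * n[2])
}

# rejection sample n centers inside the frame (with margin) but outside all
# ROIs of the given camera geometry
sample_outside_rois <- function(n, rois, frame_size, margin = 10) {
  out <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  guard <- 0
  while (length(need) > 0 && guard < 1000) {
    m <- length(need)
    cand <- cbind(stats::runif(m, margin, frame_size[1] - margin),
                  stats::runif(m, margin, frame_size[2] - margin))
    inside <- Reduce(`|`, lapply(rois, function(r) point_in_roi(cand, r)))
    ok <- !inside
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
    guard <- guard + 1
  }
  if (length(need) > 0) {
    stop("cannot place distracted poses: regions of interest cover the frame",
         call. = FALSE)
  }
  out
}

#' Simulate a behavioral session
#'
#' Generates the trial timeline, the latent engagement process, ground-truth
#' trial labels, and (optionally) per-camera detection streams with
#' occlusion dropout. Ground-truth labels are recomputed from the latent
#' per-frame poses by the same any-frame rule the scorer uses, so a
#' dropout-free pipeline run must reproduce them exactly.
#'
#' @param cfg A [sim_config()].
#' @param classifier A [classifier_config()]; defaults to
#'   [default_classifier_config()] for the configured cameras/frame size.
#' @return List: `windows` (trial-event table), `streams` (named list of
#'   per-camera detection logs; `NULL` when `generate_frames = FALSE`),
#'   `truth` (data frame `trial_index`, `state`, `label`), `classifier`,
#'   `cfg`, `session_end_s`.
#' @export
simulate_session <- function(cfg, classifier = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  cams <- paste0("cam", seq_len(cfg$n_cameras))
  if (is.null(classifier)) {
    classifier <- default_classifier_config(cfg$frame_size, cameras = cams)
  }
  for (cam in cams) {
    if (!(cam %in% cameras_of(classifier))) {
      stop("classifier lacks geometry for camera ", cam, call. = FALSE)
    }
    rr <- rois_for_camera(classifier, cam)
    if (length(rr) == 0) stop("classifier lacks an ROI for camera ", cam, call. = FALSE)
    for (r in rr) {
      if (abs(polygon_area(r$vertices)) < cfg$marker_size_px^2) {
        stop("region of interest too small to hold the marker", call. = FALSE)
      }
    }
  }
  with_local_seed(cfg$seed, {
    cyc <- cfg$trial_active_s + cfg$trial_inter_s
    n_trials <- floor(cfg$session_min * 60 / cyc)
    if (n_trials < 1) stop("session too short for a single trial", call. = FALSE)
    windows <- trial_windows(n_trials, cfg$trial_active_s, cfg$trial_inter_s,
                             trial_type = sample(c("go", "no_go"), n_trials,
                                                 replace = TRUE))
    act <- windows[windows$kind == "active", ]
    state <- rep("engaged", n_trials)
    if (!is.null(cfg$disengagement_min)) {
      state[act$start_s >= cfg$disengagement_min * 60] <- "distracted"
    }
    label <- ifelse(stats::runif(n_trials) < cfg$p_engaged[state],
                    "engaged", "distracted")
    truth <- data.frame(trial_index = act$trial_index, state = state,
                        label = label)
    session_end_s <- n_trials * cyc
    streams <- NULL
    if (cfg$generate_frames) {
      streams <- simulate_streams(cfg, classifier, truth, cams,
                                  n_trials, cyc)
      # ground truth from latent frames by the any-frame rule (pre-dropout)
      latent <- attr(streams, "latent")
      eng_by_trial <- tapply(latent$engaged[latent$active],
                             latent$trial[latent$active], max)
      truth$label <- as.character(
        ifelse(as.vector(eng_by_trial[as.character(truth$trial_index)]) > 0,
               "engaged", "distracted"))
      attr(streams, "latent") <- NULL
    }
    list(windows = windows, streams = streams, truth = truth,
         classifier = classifier, cfg = cfg, session_end_s = session_end_s)
  })
}

simulate_streams <- function(cfg, classifier, truth, cams, n_trials, cyc) {
  cam0 <- cams[1]
  rois <- rois_for_camera(classifier, cam0)
  wall <- classifier$walls[[cam0]]
  s <- cfg$marker_size_px
  ymin <- classifier$yaw_min; ymax <- classifier$yaw_max
  # per-trial base poses
  lab_eng <- truth$label == "engaged"
  n_eng <- sum(lab_eng); n_dis <- n_trials - n_eng
  base_center <- matrix(NA_real_, n_trials, 2)
  base_yaw <- numeric(n_trials)
  roi_margin <- min(15, s / 2)
  if (n_eng > 0) {
    base_center[lab_eng, ] <- sample_in_polygon(n_eng, rois[[1]],
                                                margin = roi_margin)
    base_yaw[lab_eng] <- stats::runif(n_eng, ymin + 5, ymax - 5)
  }
  if (n_dis > 0) {
    # half violate the ROI gate, half the yaw gate
    mode_roi <- rep(c(TRUE, FALSE), length.out = n_dis)
    idx <- which(!lab_eng)
    i_roi <- idx[mode_roi]; i_yaw <- idx[!mode_roi]
    if (length(i_roi) > 0) {
      base_center[i_roi, ] <- sample_outside_rois(length(i_roi), rois,
                                                  cfg$frame_size)
      base_yaw[i_roi] <- stats::runif(length(i_roi), ymin + 5, ymax - 5)
    }
    if (length(i_yaw) > 0) {
      base_center[i_yaw, ] <- sample_in_polygon(length(i_yaw), rois[[1]],
                                                margin = roi_margin)
      base_yaw[i_yaw] <- stats::runif(length(i_yaw), -170, -10)
    }
  }
  # frame grid
  n_frames <- floor(n_trials * cyc * cfg$fps)
  fidx <- seq_len(n_frames) - 1L
  t_s <- fidx / cfg$fps
  trial <- pmin(floor(t_s / cyc) + 1, n_trials)
  phase <- t_s - (trial - 1) * cyc
  active <- phase < cfg$trial_active_s
  # within-trial jitter around the base pose, kept on the correct side of
  # both gates (invalid jitters revert to the base)
  cx <- base_center[trial, 1] + stats::rnorm(n_frames, 0, 2)
  cy <- base_center[trial, 2] + stats::rnorm(n_frames, 0, 2)
  yaw <- base_yaw[trial] + stats::rnorm(n_frames, 0, 2)
  frame_eng <- lab_eng[trial]
  in_roi <- Reduce(`|`, lapply(rois, function(r) point_in_roi(cbind(cx, cy), r)))
  # engaged frames must stay in the ROI; ROI-violating distracted frames
  # must stay out of it (yaw-violating distracted trials carry negative yaw)
  dis_roi_mode <- !frame_eng & base_yaw[trial] >= 0
  bad_center <- (frame_eng & !in_roi) | (dis_roi_mode & in_roi)
  cx[bad_center] <- base_center[trial[bad_center], 1]
  cy[bad_center] <- base_center[trial[bad_center], 2]
  yaw_ok_band <- frame_eng | dis_roi_mode
  yaw[yaw_ok_band] <- pmin(pmax(yaw[yaw_ok_band], ymin + 1), ymax - 1)
  yaw[!yaw_ok_band] <- pmin(pmax(yaw[!yaw_ok_band], -175), -5)
  h <- heading_from_yaw(yaw, wall)
  ux <- -h[, 2]; uy <- h[, 1]
  hs <- s / 2
  corners <- cbind(
    c0x = cx + hs * h[, 1] - hs * ux, c0y = cy + hs * h[, 2] - hs * uy,
    c1x = cx + hs * h[, 1] + hs * ux, c1y = cy + hs * h[, 2] + hs * uy,
    c2x = cx - hs * h[, 1] + hs * ux, c2y = cy - hs * h[, 2] + hs * uy,
    c3x = cx - hs * h[, 1] - hs * ux, c3y = cy - hs * h[, 2] - hs * uy)
  latent <- data.frame(trial = trial, active = active,
                       engaged = as.integer(frame_eng))
  streams <- stats::setNames(vector("list", length(cams)), cams)
  for (ci in seq_along(cams)) {
    drop <- stats::runif(n_frames) < cfg$dropout_prob[ci]
    log <- data.frame(session_id = sprintf("sim-%d", cfg$seed),
                      camera_id = cams[ci], frame_index = fidx,
                      timestamp_s = t_s,
                      detected = as.integer(!drop),
                      marker_id = ifelse(drop, NA_integer_,
                                         classifier$target_marker_id))
    for (k in 1:8) {
      log[[detection_log_cols[6 + k]]] <- ifelse(drop, NA_real_, corners[, k])
    }
    streams[[ci]] <- log
  }
  attr(streams, "latent") <- latent
  streams
}

#' Render simulated frames to PNG files
#'
#' Rasterizes the first `max_frames` frames of a simulated stream as
#' grayscale PNGs named `<camera>_<frameindex>.png`, so the full
#' render-detect path can be exercised on simulator output. Undetected
#' (occluded) frames are rendered as background only.
#'
#' @param sim Result of [simulate_session()].
#' @param dir Output directory (created if needed).
#' @param camera Camera id to render.
#' @param max_frames Cap on rendered frames.
#' @param blur_kernel Linear motion-blur kernel, pixels.
#' @return Invisibly, a data frame with `frame_index`, `path`, and
#'   `rendered` (`FALSE` for occluded frames and poses too close to the
#'   frame edge to rasterize, which are written as background).
#' @export
render_session_frames <- function(sim, dir, camera = "cam1", max_frames = 25,
                                  blur_kernel = 0) {
  log <- sim$streams[[camera]]
  if (is.null(log)) stop("no stream for camera ", camera, call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- min(nrow(log), max_frames)
  dict <- marker_dictionary()
  bmp <- marker_bitmap(sim$classifier$target_marker_id, dict)
  fs <- sim$cfg$frame_size
  paths <- character(n)
  rendered <- logical(n)
  for (i in seq_len(n)) {
    path <- file.path(dir, sprintf("%s_%d.png", camera, log$frame_index[i]))
    if (log$detected[i] == 1) {
      corners <- matrix(as.numeric(log[i, detection_log_cols[7:14]]), 4, 2,
                        byrow = TRUE)
      ctr <- colMeans(corners)
      # rotation angle from the planted heading
      mid <- (corners[1, ] + corners[2, ]) / 2
      hvec <- mid - ctr
      ang <- atan2(hvec[1], -hvec[2]) * 180 / pi
      res <- try(render_marker_frame(bmp, ctr, ang, sim$cfg$marker_size_px,
                                     frame_size = fs,
                                     blur_kernel = blur_kernel),
                 silent = TRUE)
      rendered[i] <- !inherits(res, "try-error")
      img <- if (rendered[i]) res$image
             else matrix(0.7, fs[2], fs[1])  # marker out of frame: background
    } else {
      img <- matrix(0.7, fs[2], fs[1])
    }
    write_frame(img, path)
    paths[i] <- path
  }
  invisible(data.frame(frame_index = log$frame_index[seq_len(n)],
                       path = paths, rendered = rendered))
}
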