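# Shared fixtures: a canonical synthetic chamber (wall on the right frame
# edge, ROI from the midline to the wall) and small constructors used across
# test files.

FRAME <- c(320, 240)

chamber_cfg <- function(cameras = "cam1", ...) {
  default_classifier_config(FRAME, cameras = cameras, ...)
}

chamber_wall <- function() {
  wall_spec(c(FRAME[1], 0), c(FRAME[1], FRAME[2]),
            interior_hint = FRAME / 2)
}

# corners of an upright-mounted marker from center, heading (unit), and side
# length; independent re-derivation of the square geometry used everywhere
corners_from_pose <- function(center, heading, size) {
  h <- heading / sqrt(sum(heading^2))
  u <- c(-h[2], h[1])
  hs <- size / 2
  rbind(center + hs * h - hs * u,
        center + hs * h + hs * u,
        center - hs * h + hs * u,
        center - hs * h - hs * u)
}

# heading that yields a given yaw against the chamber wall (wall direction
# (0,1), inward normal (1,0))
heading_for_yaw <- function(yaw_deg) {
  th <- yaw_deg * pi / 180
  c(sin(th), cos(th))
}

obs_at <- function(center, yaw_deg, camera = "cam1", frame = 0, t = 0,
                   size = 40, marker_id = 0) {
  marker_observation(camera, frame, t, marker_id,
                     corners_from_pose(center, heading_for_yaw(yaw_deg), size))
}

# minimal detection-log rows for hand-built scoring scenarios
log_frame <- function(camera, frame, t, engaged = NA, center = c(240, 120),
                      yaw = 90, size = 40, detected = !is.na(engaged)) {
  if (detected) {
    yaw_use <- if (isTRUE(engaged == 1)) yaw else -90
    detection_log_row("test", camera, frame, t, marker_id = 0,
                      corners = corners_from_pose(center,
                                                  heading_for_yaw(yaw_use),
                                                  size))
  } else {
    detection_log_row("test", camera, frame, t)
  }
}

empty_detection_log_with_engaged <- function() {
  log <- empty_detection_log()
  log$engaged <- integer()
  log
}

# brute-force causal-window trace oracle: direct enumeration, independent of
# engagement_trace()
trace_oracle <- function(start_s, engaged, window_min = 5, step_min = 1,
                         end_min = max(start_s) / 60) {
  t_eval <- seq(step_min, by = step_min,
                length.out = max(1, ceiling(end_min / step_min - 1e-9)))
  start_min <- start_s / 60
  probs <- sapply(t_eval, function(t) {
    inw <- which(start_min > t - window_min & start_min <= t)
    if (length(inw) == 0) return(NA_real_)
    100 * sum(engaged[inw]) / length(inw)
  })
  data.frame(eval_min = t_eval, prob_pct = probs)
}

first_crossing_oracle <- function(start_s, engaged, threshold = 50, ...) {
  tr <- trace_oracle(start_s, engaged, ...)
  hit <- which(!is.na(tr$prob_pct) & tr$prob_pct < threshold)
  if (length(hit) == 0) NA_real_ else tr$eval_min[hit[1]]
}

# textbook confusion-metric formulas, written independently of
# compute_metrics()
metrics_oracle <- function(TP, TN, FP, FN) {
  n <- TP + TN + FP + FN
  pr <- if (TP + FP == 0) NA_real_ else 100 * TP / (TP + FP)
  se <- if (TP + FN == 0) NA_real_ else 100 * TP / (TP + FN)
  sp <- if (TN + FP == 0) NA_real_ else 100 * TN / (TN + FP)
  f1 <- if (is.na(pr) || is.na(se) || pr + se == 0) NA_real_ else
    2 * pr * se / (pr + se)
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  list(accuracy = 100 * (TP + TN) / n, precision = pr, sensitivity = se,
       specificity = sp, f1 = f1, mcc = mcc)
}
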