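test_that("frame classification applies the ROI gate and the yaw window", {
  cfg <- chamber_cfg("cam1")
  in_roi <- c(240, 120)   # inside [160, 320] x [0, 240]
  out_roi <- c(60, 120)
  expect_equal(classify_frame(obs_at(in_roi, 90), cfg), "engaged")
  expect_equal(classify_frame(obs_at(in_roi, 3), cfg), "distracted")
  expect_equal(classify_frame(NULL, cfg), "distracted")     # occlusion
  expect_equal(classify_frame(obs_at(out_roi, 90), cfg), "distracted")
  # closed endpoints of the yaw window count as engaged
  expect_equal(classify_frame(obs_at(in_roi, 5), cfg), "engaged")
  expect_equal(classify_frame(obs_at(in_roi, 175), cfg), "engaged")
  expect_equal(classify_frame(obs_at(in_roi, 4.99), cfg), "distracted")
  expect_error(classify_frame(obs_at(in_roi, 90, camera = "cam9"), cfg),
               "cam9")
})

test_that("vectorized log classification matches the scalar classifier", {
  cfg <- chamber_cfg("cam1")
  set.seed(31)
  rows <- lapply(1:40, function(i) {
    log_frame("cam1", i - 1, (i - 1) / 10,
              engaged = sample(c(1, 0, NA), 1),
              center = runif(2, c(170, 20), c(300, 220)),
              yaw = runif(1, 10, 170))
  })
  log <- do.call(rbind, rows)
  cls <- classify_detections(log, cfg)
  want <- vapply(seq_len(nrow(log)), function(i) {
    if (log$detected[i] == 0) return(0L)
    as.integer(classify_frame(log_row_to_observation(log[i, ]), cfg) == "engaged")
  }, integer(1))
  expect_equal(cls$engaged, want)
})

test_that("any-frame rule scores a trial engaged from a single frame", {
  win <- data.frame(trial_index = 1, kind = "active", start_s = 0, end_s = 6,
                    trial_type = "go")
  frames <- do.call(rbind, lapply(0:3, function(i)
    log_frame("cam1", i, i * 1.5, engaged = c(0, 0, 1, 0)[i + 1])))
  frames$engaged <- c(0L, 0L, 1L, 0L)
  s <- score_trial(frames, win)
  expect_equal(s$label, "engaged")
  expect_equal(s$n_frames_engaged, 1)
  expect_equal(s$first_engaged_s, 3.0)

  frames$engaged <- 0
  expect_equal(score_trial(frames, win)$label, "distracted")

  empty <- score_trial(frames[0, ], win)
  expect_equal(empty$label, "distracted")
  expect_equal(empty$n_frames_seen, 0)

  win0 <- win; win0$end_s <- win0$start_s
  expect_error(score_trial(frames, win0), "zero-length")
})

test_that("annotation colors encode trial phase and engagement state", {
  expect_equal(annotation_state("active", "engaged"), "green")
  expect_equal(annotation_state("active", "distracted"), "yellow")
  expect_equal(annotation_state("inter_trial", "engaged"), "purple")
  expect_equal(annotation_state("inter_trial", "distracted"), "pink")
  expect_error(annotation_state("sleep", "engaged"))
})

test_that("session scoring labels each active trial, ignoring inter-trial frames", {
  cfg <- chamber_cfg("cam1")
  windows <- trial_windows(3, active_s = 6, inter_s = 3)
  # engaged pose only during trial 2's active window; engaged pose during
  # trial 1's INTER-trial period must not score
  frames <- rbind(
    log_frame("cam1", 0, 1.0, engaged = 0),
    log_frame("cam1", 1, 7.0, engaged = 1),    # inter-trial of trial 1
    log_frame("cam1", 2, 10.0, engaged = 1),   # active trial 2
    log_frame("cam1", 3, 19.0, engaged = 0))
  scores <- score_session(frames, windows, cfg)
  expect_equal(scores$label, c("distracted", "engaged", "distracted"))

  # a session with no frames at all: every trial distracted
  none <- score_session(empty_detection_log_with_engaged(), windows, cfg)
  expect_equal(none$label, rep("distracted", 3))
})

test_that("frames outside all windows are ignored with a message", {
  cfg <- chamber_cfg("cam1")
  windows <- trial_windows(1)
  frames <- rbind(log_frame("cam1", 0, 2, engaged = 1),
                  log_frame("cam1", 1, 100, engaged = 1))
  expect_message(s <- score_session(frames, windows, cfg), "outside")
  expect_equal(s$label, "engaged")
})

test_that("scoring is monotone in engaged evidence", {
  cfg <- chamber_cfg("cam1")
  windows <- trial_windows(4)
  set.seed(32)
  frames <- do.call(rbind, lapply(0:35, function(i)
    log_frame("cam1", i, i, engaged = rbinom(1, 1, 0.2))))
  base <- score_session(frames, windows, cfg)
  # adding an engaged frame never flips engaged -> distracted
  extra <- rbind(frames, log_frame("cam1", 99, 9.5, engaged = 1))
  more <- score_session(extra, windows, cfg)
  expect_true(all(!(base$label == "engaged" & more$label == "distracted")))
  expect_equal(more$label[2], "engaged")
  # removing frames never flips distracted -> engaged
  cls <- classify_detections(frames, cfg)
  fewer <- score_session(cls[cls$engaged == 0, ], windows, cfg)
  expect_true(all(!(base$label == "distracted" & fewer$label == "engaged")))
})

test_that("fused scoring equals the OR of per-camera trial labels", {
  scfg <- sim_config(seed = 33, session_min = 4, fps = 5,
                     p_engaged = c(engaged = 0.7, distracted = 0.05),
                     dropout_prob = c(0.5, 0.5))
  sim <- simulate_session(scfg)
  per_cam <- lapply(sim$streams, function(s)
    score_session(s, sim$windows, sim$classifier)$label)
  fused <- fuse_streams(sim$streams, frame_period = 1 / 5)
  both <- score_session(fused$frames, sim$windows, sim$classifier)$label
  or_labels <- ifelse(per_cam[[1]] == "engaged" | per_cam[[2]] == "engaged",
                      "engaged", "distracted")
  expect_equal(both, or_labels)
})

test_that("trial windows validate timing and overlap", {
  w <- trial_windows(5)
  expect_equal(nrow(w), 10)
  expect_equal(w$end_s[w$kind == "active"] - w$start_s[w$kind == "active"],
               rep(6, 5))
  bad <- w; bad$end_s[1] <- bad$start_s[1]
  expect_error(arutrack:::validate_trial_windows(bad), "end > start")
  overlap <- data.frame(trial_index = 1:2, kind = "active",
                        start_s = c(0, 3), end_s = c(6, 9), trial_type = "go")
  expect_error(arutrack:::validate_trial_windows(overlap), "overlap")
})
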