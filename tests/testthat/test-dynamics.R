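trial_series <- function(labels, period_s = 9, t0 = 0) {
  data.frame(start_s = t0 + (seq_along(labels) - 1) * period_s,
             label = ifelse(labels == 1, "engaged", "distracted"))
}

test_that("probability of engagement is the engaged-trial percentage", {
  expect_equal(probability_of_engagement(941, 989), 95.15, tolerance = 5e-3)
  expect_equal(round(probability_of_engagement(941, 989), 2), 95.15)
  expect_equal(probability_of_engagement(0, 37), 0)
  expect_equal(probability_of_engagement(37, 37), 100)
  expect_warning(p0 <- probability_of_engagement(0, 0), "undefined")
  expect_true(is.na(p0))
  expect_error(probability_of_engagement(5, 3))
})

test_that("all-engaged sessions hold 100% and never disengage", {
  ser <- trial_series(rep(1, 200))
  tr <- engagement_trace(ser, dynamics_config())
  expect_true(all(tr$prob_pct[tr$defined] == 100))
  expect_true(is.na(disengagement_time(tr, dynamics_config())))
})

test_that("alternating labels hover at 50% up to one-trial quantization", {
  ser <- trial_series(rep(c(1, 0), 150))
  tr <- engagement_trace(ser, dynamics_config())
  def <- tr[tr$defined, ]
  expect_true(all(abs(def$prob_pct - 50) <= 100 / def$n_trials))
})

test_that("trace and disengagement match the brute-force window oracle", {
  # hard switch at 70 min, trials every 9 s
  starts <- seq(0, 80 * 60 - 9, by = 9)
  eng <- as.integer(starts < 70 * 60)
  ser <- data.frame(start_s = starts,
                    label = ifelse(eng == 1, "engaged", "distracted"))
  tr <- engagement_trace(ser, dynamics_config(), session_end_s = 80 * 60)
  want <- trace_oracle(starts, eng, end_min = 80)
  expect_equal(tr$eval_min, want$eval_min)
  expect_equal(tr$prob_pct, want$prob_pct)
  expect_equal(disengagement_time(tr, dynamics_config()), 73)
  expect_equal(first_crossing_oracle(starts, eng, end_min = 80), 73)
})

test_that("sub-threshold stationary engagement disengages at the first evaluation", {
  # repeating EEDDD at 6 s spacing, offset so no trial hits a window
  # boundary: every window holds whole pattern blocks, hence exactly 40%
  ser <- trial_series(rep(c(1, 1, 0, 0, 0), 80), period_s = 6, t0 = 1)
  tr <- engagement_trace(ser, dynamics_config())
  expect_true(all(abs(tr$prob_pct[tr$defined] - 40) < 1e-9))
  expect_equal(disengagement_time(tr, dynamics_config()), 1)
})

test_that("startup windows are truncated and empty windows stay undefined", {
  # first trial only at minute 10: early windows hold no trials
  ser <- data.frame(start_s = c(600, 609, 618),
                    label = c("engaged", "engaged", "distracted"))
  tr <- engagement_trace(ser, dynamics_config(), session_end_s = 660)
  expect_true(all(!tr$defined[tr$eval_min < 10]))
  expect_true(all(is.na(tr$prob_pct[!tr$defined])))
  expect_true(all(tr$truncated[tr$eval_min < 5]))
  # defined windows never read 0% merely because they are empty
  expect_true(all(tr$n_trials[tr$defined] > 0))
})

test_that("stationary Bernoulli labels average to the generating rate", {
  set.seed(41)
  ser <- trial_series(rbinom(4000, 1, 0.7), period_s = 9)
  tr <- engagement_trace(ser, dynamics_config())
  expect_lt(abs(mean(tr$prob_pct[tr$defined]) - 70), 2)
})

test_that("time translation shifts the trace content equivalently", {
  set.seed(42)
  labels <- rbinom(300, 1, 0.6)
  a <- engagement_trace(trial_series(labels), dynamics_config(),
                        session_end_s = 300 * 9)
  b <- engagement_trace(trial_series(labels, t0 = 7 * 60), dynamics_config(),
                        session_end_s = 300 * 9 + 7 * 60)
  # shifting by a whole number of steps relabels the grid but not the values
  shift <- 7
  expect_equal(b$prob_pct[(shift + 1):nrow(b)],
               a$prob_pct[1:(nrow(b) - shift)])
})

test_that("planted changepoints are recovered within one window length", {
  set.seed(43)
  for (i in 1:10) {
    tau <- runif(1, 10, 40)
    starts <- seq(0, (tau + 10) * 60, by = 9)
    eng <- as.integer(starts < tau * 60)
    ser <- data.frame(start_s = starts,
                      label = ifelse(eng == 1, "engaged", "distracted"))
    tr <- engagement_trace(ser, dynamics_config(),
                           session_end_s = max(starts) + 9)
    d <- disengagement_time(tr, dynamics_config())
    expect_gte(d, tau)
    expect_lte(d, tau + 5)
    expect_equal(d, first_crossing_oracle(starts, eng,
                                          end_min = (max(starts) + 9) / 60))
  }
})

test_that("sustained-crossing option delays the call until the run is long enough", {
  ser <- trial_series(c(rep(1, 40), 0, rep(1, 5), rep(0, 40)), period_s = 9)
  cfg1 <- dynamics_config(min_consecutive = 1)
  cfg3 <- dynamics_config(min_consecutive = 3)
  tr <- engagement_trace(ser, cfg1)
  expect_lte(disengagement_time(tr, cfg1), disengagement_time(tr, cfg3))
})

test_that("degenerate series are rejected", {
  expect_error(engagement_trace(data.frame(start_s = numeric(),
                                           label = character())), "empty")
  dup <- data.frame(start_s = c(0, 0), label = c("engaged", "engaged"))
  expect_error(engagement_trace(dup), "strictly increasing")
  expect_error(dynamics_config(window_min = 0))
  expect_error(dynamics_config(threshold_pct = 100))
})
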