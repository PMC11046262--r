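# Engagement dynamics: causal rectangular-kernel probability-of-engagement
# trace over per-trial labels, and threshold-crossing disengagement time.
#
# "Back-heavy" means the kernel is causal: the estimate at evaluation time t
# averages only the trailing window (t - L, t], so it could be computed live
# during a session. Trials are assigned to windows by their active-period
# start time. Startup windows (t < L) are truncated at the session start and
# flagged; windows holding zero trials yield missing values, never 0%,
# because a spurious 0 would immediately trigger the disengagement rule.

#' Probability of engagement
#'
#' Percentage of trials labeled engaged among the trials considered:
#' `100 * n_engaged / n_total`.
#'
#' @param n_engaged,n_total Trial counts, `0 <= n_engaged <= n_total`.
#' @return Percent in [0, 100]; `NA` when `n_total` is 0 (undefined, not 0).
#' @examples
#' probability_of_engagement(941, 989)  # 95.15
#' @export
probability_of_engagement <- function(n_engaged, n_total) {
  stopifnot(all(n_engaged >= 0), all(n_total >= 0), all(n_engaged <= n_total))
  out <- ifelse(n_total >= 1, 100 * n_engaged / n_total, NA_real_)
  if (any(n_total < 1)) {
    warning("probability of engagement undefined for empty windows (NA)",
            call. = FALSE)
  }
  out
}

#' Dynamics configuration
#'
#' Parameters of the windowed engagement analysis: kernel window length
#' (default 5 min), evaluation step (default 1 min), and the disengagement
#' threshold (default 50%). `min_consecutive` optionally requires the
#' probability to stay below threshold for several consecutive evaluation
#' points before declaring disengagement (default 1: first crossing).
#'
#' @param window_min Kernel window length, minutes.
#' @param step_min Evaluation step, minutes.
#' @param threshold_pct Disengagement threshold, percent in (0, 100).
#' @param min_consecutive Consecutive below-threshold evaluations required.
#' @return Object of class `dynamics_config`.
#' @export
dynamics_config <- function(window_min = 5, step_min = 1, threshold_pct = 50,
                            min_consecutive = 1) {
  stopifnot(window_min > 0, step_min > 0,
            threshold_pct > 0, threshold_pct < 100, min_consecutive >= 1)
  structure(list(window_min = window_min, step_min = step_min,
                 threshold_pct = threshold_pct,
                 min_consecutive = as.integer(min_consecutive)),
            class = "dynamics_config")
}

#' Windowed probability-of-engagement trace
#'
#' Slides a causal rectangular kernel over the per-trial engagement labels:
#' at each evaluation time t = step, 2*step, ... up to the session end, the
#' probability of engagement is computed over trials whose active period
#' starts inside (t - window, t], truncated at the session start.
#'
#' @param series Data frame with `start_s` (trial active start, seconds) and
#'   `label` (`engaged`/`distracted`), e.g. a trial-score table joined to
#'   its windows; [session_series()] builds one.
#' @param cfg A [dynamics_config()].
#' @param session_end_s Session end in seconds; defaults to the last trial
#'   start.
#' @return Data frame of class `engagement_trace`: `eval_min`, `n_trials`,
#'   `prob_pct` (`NA` where the window holds no trials), `defined`,
#'   `truncated` (startup windows shorter than the full kernel).
#' @export
engagement_trace <- function(series, cfg = dynamics_config(),
                             session_end_s = NULL) {
  stopifnot(inherits(cfg, "dynamics_config"))
  if (nrow(series) == 0) stop("empty engagement series", call. = FALSE)
  if (any(duplicated(series$start_s))) {
    stop("trial start times must be strictly increasing", call. = FALSE)
  }
  series <- series[order(series$start_s), , drop = FALSE]
  start_min <- series$start_s / 60
  eng <- series$label == "engaged"
  end_min <- if (is.null(session_end_s)) max(start_min) else session_end_s / 60
  t_eval <- seq(cfg$step_min, by = cfg$step_min,
                length.out = max(1, ceiling(end_min / cfg$step_min - 1e-9)))
  n_tr <- integer(length(t_eval)); n_en <- integer(length(t_eval))
  for (k in seq_along(t_eval)) {
    lo <- t_eval[k] - cfg$window_min
    inw <- start_min > lo & start_min <= t_eval[k]
    n_tr[k] <- sum(inw); n_en[k] <- sum(inw & eng)
  }
  prob <- rep(NA_real_, length(t_eval))
  prob[n_tr > 0] <- 100 * n_en[n_tr > 0] / n_tr[n_tr > 0]
  out <- data.frame(eval_min = t_eval, n_trials = n_tr, prob_pct = prob,
                    defined = n_tr > 0,
                    truncated = t_eval < cfg$window_min)
  class(out) <- c("engagement_trace", class(out))
  out
}

#' Disengagement time from a trace
#'
#' The animal counts as fully disengaged at the earliest evaluation time
#' whose defined probability of engagement falls below the threshold
#' (first crossing; `min_consecutive > 1` requires a sustained run of
#' defined below-threshold evaluations).
#'
#' @param trace Trace from [engagement_trace()].
#' @param cfg The [dynamics_config()] used to build the trace.
#' @return Disengagement time in minutes, or `NA` if engagement never falls
#'   below threshold.
#' @export
disengagement_time <- function(trace, cfg = dynamics_config()) {
  below <- trace$defined & !is.na(trace$prob_pct) &
    trace$prob_pct < cfg$threshold_pct
  m <- cfg$min_consecutive
  if (m == 1) {
    hit <- which(below)
    return(if (length(hit) > 0) trace$eval_min[hit[1]] else NA_real_)
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= m)
  if (length(ok) == 0) return(NA_real_)
  trace$eval_min[starts[ok[1]]]
}

#' Build an engagement series from scores and windows
#'
#' Joins a trial-score table to its trial windows, yielding the
#' (start time, label) series the dynamics analysis consumes.
#'
#' @param scores Trial scores from [score_session()].
#' @param windows Trial windows (see [trial_windows()]).
#' @return Data frame with `trial_index`, `start_s`, `label`.
#' @export
session_series <- function(scores, windows) {
  act <- windows[windows$kind == "active", c("trial_index", "start_s")]
  out <- merge(act, scores[, c("trial_index", "label")], by = "trial_index")
  out <- out[order(out$start_s), ]
  rownames(out) <- NULL
  out
}
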