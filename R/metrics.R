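# Validation arithmetic: confusion matrix, classification metrics, Matthews
# correlation coefficient, and the motion-blur velocity model.

#' Confusion matrix
#'
#' Counts of agreement between the automatic classifier and the manual
#' (human-scored) reference, with engaged as the positive class and
#' distracted as the negative class.
#'
#' @param TP,TN,FP,FN Non-negative counts; the total must be at least 1.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("confusion-matrix counts must be non-negative", call. = FALSE)
  if (sum(counts) < 1) stop("confusion matrix must contain at least one trial", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2,
              dimnames = list(truth = c("engaged", "distracted"),
                              predicted = c("engaged", "distracted")))
  print(m)
  invisible(x)
}

#' Confusion matrix from paired label vectors
#'
#' @param predicted,truth Character vectors of `"engaged"`/`"distracted"`
#'   labels of equal length (engaged = positive).
#' @return A [confusion_matrix()].
#' @export
confusion_from_labels <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' must have equal length", call. = FALSE)
  }
  if (length(predicted) < 1) stop("need at least one trial", call. = FALSE)
  lv <- c("engaged", "distracted")
  if (!all(predicted %in% lv) || !all(truth %in% lv)) {
    stop("labels must be 'engaged' or 'distracted'", call. = FALSE)
  }
  p <- predicted == "engaged"; t_ <- truth == "engaged"
  confusion_matrix(TP = sum(p & t_), TN = sum(!p & !t_),
                   FP = sum(p & !t_), FN = sum(!p & t_))
}

#' Confusion matrix from published marginals
#'
#' A 2x2 confusion matrix is uniquely determined by the total trial count,
#' the number of truly positive (manually engaged) trials, the number of
#' predicted-positive trials, and the false-negative count:
#' `TP = truth_pos - FN`, `FP = pred_pos - TP`,
#' `TN = total - truth_pos - FP`. The redundant constraint
#' `TN + FN = total - pred_pos` is verified and inconsistent marginals are
#' an error.
#'
#' @param total Total number of trials.
#' @param truth_pos Manually scored engaged trials.
#' @param pred_pos Automatically scored engaged trials.
#' @param FN False negatives.
#' @return A [confusion_matrix()].
#' @examples
#' confusion_from_marginals(989, 941, 952, 3)
#' @export
confusion_from_marginals <- function(total, truth_pos, pred_pos, FN) {
  TP <- truth_pos - FN
  FP <- pred_pos - TP
  TN <- total - truth_pos - FP
  if (min(TP, FP, TN, FN) < 0 || TN + FN != total - pred_pos) {
    stop("inconsistent confusion-matrix marginals", call. = FALSE)
  }
  confusion_matrix(TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, sensitivity, specificity, and F1 (all in
#' percent) plus the Matthews correlation coefficient:
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' Zero-denominator conventions: precision is `NA` when no trial is
#' predicted positive, sensitivity when there are no true positives plus
#' false negatives, specificity when `TN + FP = 0`, F1 when either
#' constituent is undefined; MCC is 0 when any marginal is zero.
#'
#' @param cm A [confusion_matrix()].
#' @param digits Rounding applied to the `rounded` element (display only;
#'   raw values are returned unrounded).
#' @return Object of class `metrics_report`: `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1` (percent), `mcc`, plus a `rounded`
#'   list at one-decimal display precision (MCC to two decimals).
#' @examples
#' compute_metrics(confusion_from_marginals(989, 941, 952, 3))
#' @export
compute_metrics <- function(cm, digits = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  total <- TP + TN + FP + FN
  accuracy <- (TP + TN) / total * 100
  precision <- if (TP + FP > 0) TP / (TP + FP) * 100 else NA_real_
  sensitivity <- if (TP + FN > 0) TP / (TP + FN) * 100 else NA_real_
  specificity <- if (TN + FP > 0) TN / (TN + FP) * 100 else NA_real_
  f1 <- if (!is.na(precision) && !is.na(sensitivity) && precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else NA_real_
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else 0
  out <- list(accuracy = accuracy, precision = precision,
              sensitivity = sensitivity, specificity = specificity,
              f1 = f1, mcc = mcc)
  out$rounded <- c(lapply(out[1:5], round, digits = digits),
                   list(mcc = round(mcc, 2)))
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  r <- x$rounded
  cat(sprintf("accuracy %.1f%%  precision %.1f%%  sensitivity %.1f%%\n",
              r$accuracy, r$precision, r$sensitivity))
  cat(sprintf("specificity %.1f%%  F1 %.1f%%  MCC %.2f\n",
              r$specificity, r$f1, r$mcc))
  invisible(x)
}

#' Motion-blur velocity model
#'
#' Converts a linear motion-blur kernel length into the marker velocity that
#' produces it: `velocity = blur_kernel_px * fps * fov_width_cm /
#' resolution_width_px` (cm/s). With the study's cameras (60 fps, 42 cm
#' field of view, 1920 px wide), a 2 px kernel - the largest blur at which
#' detection is unimpaired - corresponds to about 3 cm/s, and a 6 px kernel
#' (complete detection deterioration) to about 8 cm/s.
#'
#' @param blur_kernel_px Blur kernel length, pixels.
#' @param fps Camera frame rate, Hz.
#' @param fov_width_cm Field-of-view width, cm.
#' @param resolution_width_px Horizontal resolution, pixels.
#' @return Velocity in cm/s.
#' @examples
#' blur_velocity(2, 60, 42, 1920)  # 2.625, ~3 cm/s
#' blur_velocity(6, 60, 42, 1920)  # 7.875, ~8 cm/s
#' @export
blur_velocity <- function(blur_kernel_px, fps, fov_width_cm,
                          resolution_width_px) {
  if (any(c(blur_kernel_px, fps, fov_width_cm, resolution_width_px) <= 0)) {
    stop("all blur-velocity parameters must be positive", call. = FALSE)
  }
  blur_kernel_px * fps * fov_width_cm / resolution_width_px
}
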