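#' Voxelwise confusion counts between two binary masks
#'
#' Compares a predicted and a reference mask voxel by voxel and returns the
#' four confusion counts. Accepts [binary_mask()] objects or plain `{0,1}`
#' arrays/matrices of identical shape.
#'
#' @param pred predicted mask.
#' @param truth reference mask.
#' @return A `confusion_counts` object: list with integer fields
#'   `TP`, `FP`, `FN`, `TN` (summing to the number of voxels compared).
#' @examples
#' p <- matrix(c(1, 1, 1, 0), 2, 2)
#' t <- matrix(c(1, 1, 0, 1), 2, 2)
#' confusion(p, t)
#' @export
confusion <- function(pred, truth) {
  p <- mask_values(pred); t <- mask_values(truth)
  if (!identical(dim(p), dim(t)))
    stop("shape mismatch between pred and truth", call. = FALSE)
  tp <- sum(p == 1L & t == 1L)
  fp <- sum(p == 1L & t == 0L)
  fn <- sum(p == 0L & t == 1L)
  tn <- length(p) - tp - fp - fn
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

mask_values <- function(m) {
  if (inherits(m, "binary_mask")) m <- m$voxels
  if (!all(m %in% c(0L, 1L))) stop("mask values must be 0/1", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Intersection-over-union of a mask comparison
#'
#' `IOU = TP / (TP + FP + FN)`, ranging over \[0, 1\]. When both masks are
#' empty (`TP + FP + FN = 0`) the score is defined as 1: perfect agreement
#' on absence. Annotated clinical slices always contain vessel, so the
#' convention only matters for synthetic or cropped inputs; per-slice
#' outputs flag it (see [evaluate_patient()]).
#'
#' @param c a `confusion_counts` object from [confusion()].
#' @return IOU in \[0, 1\].
#' @export
iou <- function(c) {
  denom <- c$TP + c$FP + c$FN
  if (denom == 0) return(1)
  c$TP / denom
}

#' Dice coefficient of a mask comparison
#'
#' `Dice = 2 TP / (2 TP + FP + FN)`; equivalently `2*iou/(1 + iou)`. Both
#' masks empty gives 1, matching the [iou()] convention.
#'
#' @inheritParams iou
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(c) {
  denom <- 2 * c$TP + c$FP + c$FN
  if (denom == 0) return(1)
  2 * c$TP / denom
}

#' Mean absolute percentage error
#'
#' `mean(|y_true - y_pred| / y_true) * 100` over paired samples. The
#' reference values must be strictly positive; a zero reference makes the
#' percentage undefined and is rejected.
#'
#' @param y_true strictly positive reference values.
#' @param y_pred predictions, same length.
#' @return MAPE in percent.
#' @examples
#' mape(c(100, 200), c(90, 220))  # 10
#' @export
mape <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    stop("y_true and y_pred must be equal-length, non-empty", call. = FALSE)
  if (any(y_true == 0))
    stop("MAPE undefined: reference value of 0 (division by zero)", call. = FALSE)
  mean(abs(y_true - y_pred) / y_true) * 100
}

#' Absolute percentage error of a single pair
#'
#' `|y_true - y_pred| / y_true * 100`; [mape()] of a vector equals the mean
#' of the elementwise `ape` values.
#'
#' @param y_true strictly positive reference value(s).
#' @param y_pred prediction(s).
#' @return APE in percent (vectorized).
#' @export
ape <- function(y_true, y_pred) {
  if (any(y_true == 0))
    stop("APE undefined: reference value of 0", call. = FALSE)
  abs(y_true - y_pred) / y_true * 100
}

#' Coefficient of determination
#'
#' `R^2 = 1 - RSS/TSS`, where RSS is the sum of squared residuals of the
#' predictions against the reference and TSS the total sum of squares of
#' the reference about its mean. A constant reference has TSS = 0 and is
#' rejected.
#'
#' @param y_true reference values (not all equal).
#' @param y_pred predictions, same length.
#' @return R-squared (1 for a perfect prediction; 0 when predicting the
#'   reference mean; can be negative for predictions worse than the mean).
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  tss <- sum((y_true - mean(y_true))^2)
  if (tss == 0) stop("R-squared undefined: constant reference (TSS = 0)", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / tss
}

#' Ordinary least-squares line through paired scores
#'
#' Fits `y ~ x` with intercept via [stats::lm()] and reports the slope,
#' intercept and R-squared of the fit — the regression summary used to
#' compare automated against manual calcium scores.
#'
#' @param x predictor values (e.g. manual scores).
#' @param y response values (e.g. automated scores).
#' @return A `regression_summary`: list with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  fit <- stats::lm(y ~ x)
  fitted_y <- stats::fitted(fit)
  tss <- sum((y - mean(y))^2)
  rsq <- if (tss == 0) stop("R-squared undefined: constant response", call. = FALSE)
         else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = rsq, n = length(x)),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("<regression_summary> y = %.4g x + %.4g, R^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Binary cross-entropy
#'
#' `-mean(y * log(p) + (1 - y) * log(1 - p))` with probabilities clamped to
#' `[eps, 1 - eps]` so saturated outputs give a finite loss.
#'
#' @param y_true labels in `{0, 1}` (any numeric shape).
#' @param y_prob predicted probabilities, same shape.
#' @param eps clamp width (default `1e-7`).
#' @return Non-negative scalar loss.
#' @examples
#' bce(c(0, 1), c(0.5, 0.5))  # log(2)
#' @export
bce <- function(y_true, y_prob, eps = 1e-7) {
  stopifnot(length(y_true) == length(y_prob))
  p <- pmin(pmax(as.numeric(y_prob), eps), 1 - eps)
  y <- as.numeric(y_true)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Per-slice overlap table for a predicted volume mask
#'
#' Computes confusion counts, Dice and IOU slice by slice (the evaluation
#' contract: per-patient accuracy is the mean of per-slice scores, never
#' pooled-voxel overlap) and returns a tidy table with one row per slice.
#' Slices where both masks are empty score 1 and are flagged.
#'
#' @param pred,truth [binary_mask()] objects of identical shape.
#' @return A data.frame with columns `slice`, `TP`, `FP`, `FN`, `TN`,
#'   `dice`, `iou`, `both_empty`.
#' @export
slice_overlap_table <- function(pred, truth) {
  check_same_geometry(pred, truth)
  ns <- dim(pred$voxels)[3L]
  rows <- lapply(seq_len(ns), function(s) {
    cc <- confusion(pred$voxels[, , s], truth$voxels[, , s])
    data.frame(slice = s, TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
               dice = dice(cc), iou = iou(cc),
               both_empty = (cc$TP + cc$FP + cc$FN) == 0L)
  })
  do.call(rbind, rows)
}
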