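# Pixel-wise and scenario-level evaluation of hotspot images.

#' Pixel-level confusion counts
#'
#' @param pred,truth logical (or 0/1) arrays of equal shape.
#' @return list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth) | is.null(dim(pred)) == is.null(dim(truth))))
    stop("shape mismatch between prediction and truth")
  p <- as.logical(pred); t <- as.logical(truth)
  if (length(p) != length(t)) stop("length mismatch")
  list(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Pixel accuracy score
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cc confusion counts from [confusion_counts()].
#' @return value in `[0, 1]`.
#' @export
accuracy_score <- function(cc) {
  d <- cc$TP + cc$TN + cc$FP + cc$FN
  if (d == 0) stop("no pixels compared")
  (cc$TP + cc$TN) / d
}

#' Dice overlap score
#'
#' `2 TP / (2 TP + FP + FN)`. When both images are all-negative the score is
#' undefined; `NA` is returned and such pairs are excluded from averages.
#'
#' @param cc confusion counts from [confusion_counts()].
#' @return value in `[0, 1]`, or `NA` when undefined.
#' @export
dice_score <- function(cc) {
  d <- 2 * cc$TP + cc$FP + cc$FN
  if (d == 0) return(NA_real_)
  2 * cc$TP / d
}

#' Scenario danger status
#'
#' `TRUE` when at least one hotspot pixel lies outside the tumor region
#' (hotspots inside the tumor are intended heating, not a danger).
#'
#' @param img logical hotspot image.
#' @param tumor logical tumor mask on the same grid.
#' @return logical scalar.
#' @export
danger_status <- function(img, tumor) {
  if (!all(dim(img) == dim(tumor))) stop("grid mismatch")
  any(as.logical(img) & !as.logical(tumor))
}

#' Scenario-level danger accuracy (recall)
#'
#' `TP_danger / (TP_danger + FN_danger)` over the truly dangerous
#' scenarios.
#'
#' @param truth_status,pred_status logical vectors per scenario.
#' @return value in `[0, 1]`.
#' @export
danger_accuracy <- function(truth_status, pred_status) {
  stopifnot(length(truth_status) == length(pred_status))
  pos <- which(truth_status)
  if (length(pos) == 0) stop("no danger-positive scenarios in the truth")
  sum(pred_status[pos]) / length(pos)
}

# Per-sample scores for a stack of binary predictions against truths.
# preds, truths: n x n x N logical arrays; tumor: n x n mask.
score_images <- function(preds, truths, tumor) {
  N <- dim(truths)[3]
  s_acc <- s_dice <- numeric(N)
  truth_danger <- pred_danger <- logical(N)
  for (i in seq_len(N)) {
    cc <- confusion_counts(preds[, , i], truths[, , i])
    s_acc[i] <- accuracy_score(cc)
    s_dice[i] <- dice_score(cc)
    truth_danger[i] <- danger_status(truths[, , i], tumor)
    pred_danger[i] <- danger_status(preds[, , i], tumor)
  }
  res <- data.frame(s_acc = s_acc, s_dice = s_dice,
                    truth_danger = truth_danger, pred_danger = pred_danger)
  structure(list(
    per_sample = res,
    mean_s_acc = mean(s_acc),
    mean_s_dice = mean(s_dice, na.rm = TRUE),
    danger_accuracy = if (any(truth_danger))
      danger_accuracy(truth_danger, pred_danger) else NA_real_,
    pixel_accuracy = {
      cc <- confusion_counts(preds, truths)
      accuracy_score(cc)
    }
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d scenarios\n", nrow(x$per_sample)))
  cat(sprintf("  pixel accuracy  %.4f\n", x$pixel_accuracy))
  cat(sprintf("  mean s_acc      %.4f\n", x$mean_s_acc))
  cat(sprintf("  mean s_Dice     %.4f  (all-negative pairs excluded)\n",
              x$mean_s_dice))
  cat(sprintf("  danger accuracy %.4f  (%d danger-positive scenarios)\n",
              x$danger_accuracy, sum(x$per_sample$truth_danger)))
  invisible(x)
}

#' Decision-threshold sweep
#'
#' Evaluates mean pixel accuracy, mean Dice and danger accuracy over a grid
#' of decision thresholds applied to probability maps. Predictions are
#' nested in the threshold, so danger accuracy is non-increasing in
#' `alpha`.
#'
#' @param probs `n x n x N` array of probability maps.
#' @param truths `n x n x N` logical array of true hotspot images.
#' @param tumor logical tumor mask.
#' @param alphas numeric vector of thresholds in (0, 1).
#' @return data.frame with one row per threshold.
#' @export
threshold_sweep <- function(probs, truths, tumor, alphas = seq(0.1, 0.9, 0.1)) {
  rows <- lapply(alphas, function(a) {
    rep <- score_images(probs > a, truths, tumor)
    data.frame(alpha = a, mean_s_acc = rep$mean_s_acc,
               mean_s_dice = rep$mean_s_dice,
               danger_accuracy = rep$danger_accuracy)
  })
  do.call(rbind, rows)
}
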