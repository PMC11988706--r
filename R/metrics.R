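# Evaluation metrics: accuracy, Dice, IoU, recall, precision, specificity,
# from the pixel confusion matrix after thresholding the probability map.

metric_from_counts <- function(tp, fp, fn, tn) {
  safe <- function(num, den, empty_ok) {
    if (den > 0) num / den else if (empty_ok) 1 else 0
  }
  # a zero denominator means the relevant ground-truth/prediction set is
  # empty; score 1 when the prediction agrees (nothing to find, nothing
  # found), else 0
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1,
    iou = if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1,
    recall = safe(tp, tp + fn, fp == 0),
    precision = safe(tp, tp + fp, fn == 0),
    specificity = safe(tn, tn + fp, fn == 0))
}

#' Segmentation metrics for one prediction
#'
#' Binarizes `P` at `threshold` and computes accuracy, Dice, IoU, recall,
#' precision and specificity from the pixel confusion counts. Ratios with a
#' zero denominator are reported as 1 when the corresponding ground-truth set
#' is empty and the prediction agrees, else 0.
#'
#' @param P Probability map (or already-binary prediction).
#' @param G Binary ground-truth mask, same shape.
#' @param threshold Binarization threshold (default 0.5).
#' @return Named numeric vector with the six metrics, each in `[0, 1]`.
#' @export
segmentation_metrics <- function(P, G, threshold = 0.5) {
  check_pg(P, G)
  pb <- P >= threshold
  gb <- G >= 0.5
  tp <- sum(pb & gb)
  fp <- sum(pb & !gb)
  fn <- sum(!pb & gb)
  tn <- sum(!pb & !gb)
  metric_from_counts(tp, fp, fn, tn)
}

#' Aggregate a set of predictions into a metric report
#'
#' Computes the six metrics for every prediction/mask pair and aggregates
#' them. The default aggregation is the per-image mean; `pooled = TRUE`
#' instead pools the confusion counts over all pixels of all images before
#' computing the metrics.
#'
#' @param preds List of probability maps.
#' @param masks List of matching binary masks.
#' @param threshold Binarization threshold.
#' @param pooled If `TRUE` also the image-pooled (global-confusion) variant
#'   is reported.
#' @return A `carunet_metric_report`: list with `per_image` (data frame, one
#'   row per image), `mean` (named vector), `aggregation` (`"image_mean"`)
#'   and optionally `pooled`.
#' @export
metric_report <- function(preds, masks, threshold = 0.5, pooled = FALSE) {
  check_that(length(preds) == length(masks) && length(preds) > 0,
             "preds/masks: need equally many predictions and masks")
  rows <- t(vapply(seq_along(preds), function(i)
    segmentation_metrics(preds[[i]], masks[[i]], threshold), numeric(6)))
  per_image <- as.data.frame(rows)
  out <- list(per_image = per_image, mean = colMeans(rows),
              aggregation = "image_mean")
  if (pooled) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(preds)) {
      pb <- preds[[i]] >= threshold
      gb <- masks[[i]] >= 0.5
      tp <- tp + sum(pb & gb); fp <- fp + sum(pb & !gb)
      fn <- fn + sum(!pb & gb); tn <- tn + sum(!pb & !gb)
    }
    out$pooled <- metric_from_counts(tp, fp, fn, tn)
  }
  structure(out, class = "carunet_metric_report")
}

#' @export
print.carunet_metric_report <- function(x, ...) {
  cat("Segmentation metrics (aggregation: ", x$aggregation, ", ",
      nrow(x$per_image), " images)\n", sep = "")
  cat(paste(sprintf("%s %.2f%%", names(x$mean), 100 * x$mean),
            collapse = "  "), "\n")
  invisible(x)
}

#' Write a metric report as CSV and JSON
#'
#' Columns follow the published table order (Accuracy, Dice, IoU, Recall,
#' Precision, Specificity), as percentages with two decimals.
#'
#' @param report A [metric_report()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The formatted data frame, invisibly.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  ord <- c("accuracy", "dice", "iou", "recall", "precision", "specificity")
  fmt <- function(v) round(100 * v[ord], 2)
  df <- as.data.frame(rbind(t(apply(report$per_image, 1, fmt)),
                            fmt(report$mean)))
  rownames(df) <- c(seq_len(nrow(report$per_image)), "mean")
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = TRUE)
  if (!is.null(json_path))
    jsonlite::write_json(list(per_image = df[-nrow(df), ],
                              mean = as.list(fmt(report$mean))),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
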