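#' Pixel confusion counts
#'
#' @param gt,pred binary masks of identical shape.
#' @return named vector `tp, fp, fn, tn` (sums to the pixel count).
#' @export
confusion_counts <- function(gt, pred) {
  check_mask(gt, "gt"); check_mask(pred, "pred")
  if (!all(dim(gt) == dim(pred))) stop("gt and pred must have the same shape")
  tp <- sum(gt == 1 & pred == 1)
  fp <- sum(gt == 0 & pred == 1)
  fn <- sum(gt == 1 & pred == 0)
  c(tp = tp, fp = fp, fn = fn, tn = length(gt) - tp - fp - fn)
}

#' Segmentation metrics for one image
#'
#' Computes accuracy, Dice similarity coefficient, intersection over union,
#' sensitivity and specificity from the pixel confusion counts:
#' accuracy `(tp+tn)/total`, Dice `2tp/(2tp+fp+fn)`, IoU `tp/(tp+fp+fn)`,
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`.
#'
#' Empty-denominator conventions: if both masks are empty, Dice, IoU and
#' sensitivity are 1 (perfect agreement); if the ground truth is empty but
#' the prediction is not, they are 0. An all-positive ground truth gives
#' specificity 1 when the prediction is also all-positive, otherwise the
#' usual ratio applies. These choices keep every metric in `[0, 1]` and
#' monotone in error.
#'
#' @param gt,pred binary masks of identical shape.
#' @return named numeric vector
#'   `accuracy, dice, iou, sensitivity, specificity`.
#' @examples
#' gt <- matrix(0L, 4, 4); gt[1:2, 1:2] <- 1L
#' pred <- matrix(0L, 4, 4); pred[1:2, 1] <- 1L
#' segmentation_metrics(gt, pred)   # dice 2*2/(4+2), iou 2/4
#' @export
segmentation_metrics <- function(gt, pred) {
  cc <- confusion_counts(gt, pred)
  tp <- cc["tp"]; fp <- cc["fp"]; fn <- cc["fn"]; tn <- cc["tn"]
  total <- sum(cc)
  safe <- function(num, den, empty_value) {
    if (den == 0) empty_value else num / den
  }
  unname_ <- function(x) as.numeric(x)
  c(accuracy = unname_((tp + tn) / total),
    dice = unname_(safe(2 * tp, 2 * tp + fp + fn, 1)),
    iou = unname_(safe(tp, tp + fp + fn, 1)),
    sensitivity = unname_(safe(tp, tp + fn, if (fp == 0) 1 else 0)),
    specificity = unname_(safe(tn, tn + fp, if (fn == 0) 1 else 0)))
}

#' Aggregate per-image metric scores
#'
#' Arithmetic mean and population standard deviation per metric, with the
#' conventional `mean±sd` cell formatting (two decimals).
#'
#' @param scores numeric vector of per-image scores for a single metric, or a
#'   matrix / data frame with one column per metric and one row per image.
#' @param percent multiply by 100 before formatting.
#' @return data frame with columns `metric`, `mean`, `sd`, `formatted`.
#' @examples
#' aggregate_metrics(c(0.6, 0.8, 1.0))   # mean 0.8, population sd 0.1633
#' @export
aggregate_metrics <- function(scores, percent = FALSE) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1,
                                             dimnames = list(NULL, "score"))
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) stop("need at least one image")
  mult <- if (percent) 100 else 1
  res <- lapply(seq_len(ncol(scores)), function(j) {
    x <- scores[, j] * mult
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))     # population sd, as in reported tables
    data.frame(metric = colnames(scores)[j], mean = m, sd = s,
               formatted = sprintf("%.2f±%.2f", m, s))
  })
  do.call(rbind, res)
}

#' Evaluate a model over a dataset
#'
#' Predicts a mask for every `(image, mask)` pair and returns the per-image
#' metric table plus the aggregate.
#'
#' @param net a [harmonic_unet()].
#' @param data list of pairs as in [train_network()].
#' @param threshold probability threshold.
#' @return list with `per_image` (data frame) and `aggregate` (data frame).
#' @export
evaluate_network <- function(net, data, threshold = 0.5) {
  if (length(data) == 0L) stop("empty evaluation dataset")
  rows <- lapply(data, function(d) {
    pr <- predict_mask(net, d$image, threshold)
    as.data.frame(t(segmentation_metrics(d$mask, pr$mask)))
  })
  per_image <- do.call(rbind, rows)
  list(per_image = per_image, aggregate = aggregate_metrics(per_image))
}
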