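# Follicle sizing, recruitable-range filtering, matching and counting.
# The sizing convention follows clinical practice: a follicle's diameter is
# the mean of its two orthogonal axis lengths, obtained here from the
# equivalent ellipse (the ellipse with the same normalized second central
# moments as the pixel region), scaled by the pixel spacing.

#' Label connected components
#'
#' @param mask binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  check_mask(mask)
  .cpp_label_components(matrix(as.integer(mask), nrow(mask)), connectivity)
}

# equivalent-ellipse axis lengths (in px) from 0-based pixel coordinates
ellipse_axes <- function(r, c) {
  mr <- mean(r); mc <- mean(c)
  crr <- mean((r - mr)^2); ccc <- mean((c - mc)^2)
  crc <- mean((r - mr) * (c - mc))
  h <- (crr + ccc) / 2
  s <- sqrt(((crr - ccc) / 2)^2 + crc^2)
  lam <- c(h + s, max(h - s, 0))
  c(major = 4 * sqrt(lam[1]), minor = 4 * sqrt(lam[2]),
    centroid_row = mr, centroid_col = mc)
}

#' Extract follicle records from a binary mask
#'
#' Labels the 8-connected components of a follicle mask and measures each
#' one: centroid, major/minor axis lengths of the equivalent ellipse, and
#' the physical diameter
#' `diameter_mm = pixel_spacing_mm * (major + minor) / 2`
#' (the average of the two orthogonal axis diameters). The `recruitable`
#' flag marks diameters in the antral 2-10 mm range.
#'
#' @param mask binary follicle mask.
#' @param pixel_spacing_mm physical pixel size in mm (> 0).
#' @param connectivity component connectivity, 8 (default) or 4.
#' @param recruitable_range_mm the antral diameter range used for the flag.
#' @return an object of class `follicle_set`: list with `records` (data
#'   frame: label, area_px, centroid_row, centroid_col, major_axis_px,
#'   minor_axis_px, diameter_mm, recruitable), `labels` (label matrix) and
#'   `spacing_mm`.
#' @export
extract_follicles <- function(mask, pixel_spacing_mm, connectivity = 8L,
                              recruitable_range_mm = c(2, 10)) {
  if (!is.numeric(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("'pixel_spacing_mm' must be positive")
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  rec <- data.frame(label = integer(0), area_px = integer(0),
                    centroid_row = double(0), centroid_col = double(0),
                    major_axis_px = double(0), minor_axis_px = double(0),
                    diameter_mm = double(0), recruitable = logical(0))
  if (n > 0) {
    idx <- which(lab > 0)
    rr <- (idx - 1L) %% nrow(lab)       # 0-based row
    cc <- (idx - 1L) %/% nrow(lab)      # 0-based col
    ll <- lab[idx]
    rows <- lapply(seq_len(n), function(k) {
      sel <- ll == k
      ax <- ellipse_axes(rr[sel], cc[sel])
      dmm <- pixel_spacing_mm * (ax[["major"]] + ax[["minor"]]) / 2
      data.frame(label = k, area_px = sum(sel),
                 centroid_row = ax[["centroid_row"]],
                 centroid_col = ax[["centroid_col"]],
                 major_axis_px = ax[["major"]], minor_axis_px = ax[["minor"]],
                 diameter_mm = dmm,
                 recruitable = dmm >= recruitable_range_mm[1] &
                   dmm <= recruitable_range_mm[2])
    })
    rec <- do.call(rbind, rows)
  }
  structure(list(records = rec, labels = lab, spacing_mm = pixel_spacing_mm),
            class = "follicle_set")
}

#' @export
print.follicle_set <- function(x, ...) {
  cat(sprintf("<follicle_set> %d component(s) at %.3g mm/px\n",
              nrow(x$records), x$spacing_mm))
  if (nrow(x$records)) print(x$records, row.names = FALSE)
  invisible(x)
}

#' Keep only recruitable follicles
#'
#' Filters a [extract_follicles()] result to components whose diameter lies
#' in `[low, high]` mm (the antral/recruitable range; below 2 mm small
#' anechoic structures such as vessels could be miscounted, above 10 mm the
#' component is a dominant follicle). Excluded components are blanked from
#' the label matrix, so downstream matching operates on the filtered mask.
#'
#' @param fs a `follicle_set`.
#' @param low,high diameter bounds in mm.
#' @return a filtered `follicle_set`.
#' @export
recruitable_filter <- function(fs, low = 2, high = 10) {
  if (!inherits(fs, "follicle_set")) stop("'fs' must be a follicle_set")
  if (low > high) stop("'low' must not exceed 'high'")
  keep <- fs$records$diameter_mm >= low & fs$records$diameter_mm <= high
  drop <- fs$records$label[!keep]
  if (length(drop)) fs$labels[fs$labels %in% drop] <- 0L
  fs$records <- fs$records[keep, , drop = FALSE]
  fs
}

#' Match predicted follicles to ground truth
#'
#' Computes the pairwise Dice coefficient between every ground-truth and
#' predicted component, then matches greedily one-to-one in descending Dice
#' order. A predicted follicle counts as correctly detected iff it is
#' matched with Dice strictly greater than `dice_threshold`.
#'
#' @param gt_fs,pred_fs `follicle_set`s from the same image geometry.
#' @param dice_threshold match threshold (default 0.5, strict).
#' @return data frame with columns `gt_label`, `pred_label`, `dice`,
#'   `correct`, one row per matched pair.
#' @export
match_follicles <- function(gt_fs, pred_fs, dice_threshold = 0.5) {
  if (!all(dim(gt_fs$labels) == dim(pred_fs$labels)))
    stop("follicle sets come from different image geometries")
  empty <- data.frame(gt_label = integer(0), pred_label = integer(0),
                      dice = double(0), correct = logical(0))
  if (!nrow(gt_fs$records) || !nrow(pred_fs$records)) return(empty)
  both <- gt_fs$labels > 0 & pred_fs$labels > 0
  if (!any(both)) return(empty)
  ov <- table(gt = gt_fs$labels[both], pred = pred_fs$labels[both])
  area_g <- stats::setNames(gt_fs$records$area_px, gt_fs$records$label)
  area_p <- stats::setNames(pred_fs$records$area_px, pred_fs$records$label)
  pairs <- as.data.frame(ov, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$Freq > 0, , drop = FALSE]
  pairs$dice <- 2 * pairs$Freq /
    (area_g[pairs$gt] + area_p[pairs$pred])
  pairs <- pairs[order(-pairs$dice), , drop = FALSE]
  used_g <- used_p <- character(0)
  out <- empty
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gt[i]; p <- pairs$pred[i]
    if (g %in% used_g || p %in% used_p) next
    used_g <- c(used_g, g); used_p <- c(used_p, p)
    out <- rbind(out, data.frame(gt_label = as.integer(g),
                                 pred_label = as.integer(p),
                                 dice = pairs$dice[i],
                                 correct = pairs$dice[i] > dice_threshold))
  }
  out
}

#' Follicle counting report
#'
#' Runs the full counting stage on a ground-truth/prediction mask pair:
#' extract components, convert axis lengths to physical diameters, drop
#' components outside the 2-10 mm recruitable range on both masks, match
#' one-to-one by Dice, and count. Precision is
#' `correctly detected / detected`, recall is `correctly detected / real`.
#' A zero denominator yields 0 for the affected rate and sets the `flagged`
#' field.
#'
#' @param gt_mask,pred_mask binary follicle masks of identical shape.
#' @param pixel_spacing_mm physical pixel size in mm.
#' @param low,high recruitable diameter range in mm.
#' @param dice_threshold per-follicle match threshold (strict).
#' @param connectivity component connectivity.
#' @return an object of class `quant_report`: list with `n_real`,
#'   `n_detected`, `n_correct`, `precision`, `recall` (fractions),
#'   `flagged`, `matches`, `gt` and `pred` (`follicle_set`s after
#'   filtering).
#' @seealso [counting_rates()] for the percentage arithmetic alone.
#' @export
counting_report <- function(gt_mask, pred_mask, pixel_spacing_mm,
                            low = 2, high = 10, dice_threshold = 0.5,
                            connectivity = 8L) {
  if (!all(dim(gt_mask) == dim(pred_mask)))
    stop("gt and pred masks must have the same shape")
  gt <- recruitable_filter(
    extract_follicles(gt_mask, pixel_spacing_mm, connectivity), low, high)
  pred <- recruitable_filter(
    extract_follicles(pred_mask, pixel_spacing_mm, connectivity), low, high)
  matches <- match_follicles(gt, pred, dice_threshold)
  n_real <- nrow(gt$records)
  n_detected <- nrow(pred$records)
  n_correct <- sum(matches$correct)
  structure(list(
    n_real = n_real, n_detected = n_detected, n_correct = n_correct,
    precision = if (n_detected > 0) n_correct / n_detected else 0,
    recall = if (n_real > 0) n_correct / n_real else 0,
    flagged = n_detected == 0 || n_real == 0,
    matches = matches, gt = gt, pred = pred), class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf(paste0("<quant_report> real %d, detected %d, correct %d | ",
                     "precision %.2f%%, recall %.2f%%%s\n"),
              x$n_real, x$n_detected, x$n_correct, 100 * x$precision,
              100 * x$recall,
              if (x$flagged) " [degenerate denominator]" else ""))
  invisible(x)
}

#' Counting precision and recall from aggregate counts
#'
#' The percentage arithmetic of the counting stage:
#' `precision = 100 * n_correct / n_detected`,
#' `recall = 100 * n_correct / n_real`.
#'
#' @param n_correct,n_detected,n_real non-negative counts.
#' @return list with `precision_pct` and `recall_pct`.
#' @examples
#' counting_rates(344, 448, 378)   # recall 91.01
#' @export
counting_rates <- function(n_correct, n_detected, n_real) {
  stopifnot(n_correct >= 0, n_detected >= 0, n_real >= 0,
            n_correct <= n_detected, n_correct <= n_real)
  list(precision_pct = if (n_detected > 0) 100 * n_correct / n_detected else 0,
       recall_pct = if (n_real > 0) 100 * n_correct / n_real else 0)
}
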