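#' Pixel-wise confusion counts
#'
#' Counts true/false positives and negatives of a predicted binary mask
#' against a reference: TP = adipose pixels correctly identified, TN =
#' background/lean correctly identified, FP = background mislabeled
#' adipose, FN = adipose missed.
#'
#' @param pred,ref Integer 0/1 matrices of identical shape.
#' @return A named list `tp`, `fp`, `fn`, `tn` (sums to the pixel count).
#' @export
confusion_counts <- function(pred, ref) {
  assert_mask(pred); assert_mask(ref)
  assert_same_shape(pred, ref, "pred", "ref")
  tp <- sum(pred == 1L & ref == 1L)
  fp <- sum(pred == 1L & ref == 0L)
  fn <- sum(pred == 0L & ref == 1L)
  tn <- sum(pred == 0L & ref == 0L)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Dice coefficient
#'
#' Overlap metric `2 TP / (2 TP + FP + FN)`, robust to class imbalance;
#' the primary accuracy metric for adipose segmentation. Two empty masks
#' are defined to agree perfectly (Dice 1); one empty mask scores 0.
#'
#' @param pred,ref Integer 0/1 matrices of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  cc <- confusion_counts(pred, ref)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  if (denom == 0) return(1)
  2 * cc$tp / denom
}

#' Hausdorff distance between masks
#'
#' Symmetric Hausdorff distance `max(h(A,B), h(B,A))` with
#' `h(A,B) = max over a in A of min over b in B of ||a - b||`, computed
#' over the full foreground pixel coordinate sets in Euclidean pixel
#' units (via exact distance transforms). `percentile` switches to the
#' robust variant using that percentile of the directed distances (e.g.
#' 95) instead of the maximum.
#'
#' @param pred,ref Non-empty integer 0/1 matrices of identical shape.
#' @param percentile Optional percentile in (0, 100] replacing the max.
#' @return Distance in pixel units, >= 0.
#' @export
hausdorff <- function(pred, ref, percentile = NULL) {
  assert_mask(pred); assert_mask(ref)
  assert_same_shape(pred, ref, "pred", "ref")
  if (sum(pred) == 0 || sum(ref) == 0) {
    stop("Hausdorff distance is undefined for an empty mask", call. = FALSE)
  }
  d_pred_to_ref <- dist_to_set(ref)[pred == 1L]
  d_ref_to_pred <- dist_to_set(pred)[ref == 1L]
  agg <- if (is.null(percentile)) {
    max
  } else {
    stopifnot(percentile > 0, percentile <= 100)
    function(d) quantile(d, percentile / 100, names = FALSE, type = 7)
  }
  max(agg(d_pred_to_ref), agg(d_ref_to_pred))
}

# Exact Euclidean distance from every pixel to the nearest foreground
# pixel of `mask`.
dist_to_set <- function(mask) {
  as_plain_matrix(EBImage::distmap(1 - mask, metric = "euclidean"))
}

#' Per-compartment evaluation report
#'
#' Scores predicted SAT/VAT/TAT masks against reference compartments:
#' Dice, Hausdorff distance and the confusion counts for each compartment.
#' The stored Dice is re-derived from the stored confusion counts so the
#' two can never disagree. Hausdorff is `NA` when either mask of a
#' compartment is empty.
#'
#' @param pred,ref [compartment_masks()] objects of identical shape.
#' @param method Method tag carried into the report.
#' @return A data.frame with one row per compartment (`tat`, `sat`, `vat`)
#'   and columns `method`, `compartment`, `dice`, `hausdorff_px`, `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
eval_report <- function(pred, ref, method = "unknown") {
  stopifnot(inherits(pred, "compartment_masks"), inherits(ref, "compartment_masks"))
  rows <- lapply(c("tat", "sat", "vat"), function(comp) {
    p <- pred[[comp]]; r <- ref[[comp]]
    cc <- confusion_counts(p, r)
    dn <- 2 * cc$tp + cc$fp + cc$fn
    dc <- if (dn == 0) 1 else 2 * cc$tp / dn
    hd <- if (sum(p) > 0 && sum(r) > 0) hausdorff(p, r) else NA_real_
    data.frame(method = method, compartment = comp, dice = dc,
               hausdorff_px = hd, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               tn = cc$tn, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
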