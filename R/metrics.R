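# Segmentation metrics: confusion counts, the five scalar metrics and the
# 95th-percentile Hausdorff boundary distance.

#' Pixelwise confusion counts
#'
#' Positive class is the lesion (1).
#'
#' @param pred,gt binary maps of equal shape with values in `{0, 1}`
#' @return list with integer fields `TP`, `FP`, `TN`, `FN`
#' @export
confusion <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("confusion: shape mismatch")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("confusion: maps must be binary")
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

safe_ratio <- function(num, den, both_absent) {
  if (den == 0) return(if (both_absent) 1.0 else 0.0)
  num / den
}

#' Scalar segmentation metrics from confusion counts
#'
#' mIoU here is the foreground intersection-over-union TP/(TP+FP+FN), as is
#' conventional in the skin-lesion literature; set `two_class_mean = TRUE`
#' for the average of foreground and background IoU. A metric whose
#' denominator is zero is 1 when the corresponding class is absent from both
#' maps and 0 otherwise.
#'
#' @param cc confusion counts from [confusion()]
#' @param two_class_mean average foreground and background IoU?
#' @return named list: `miou`, `dsc`, `acc`, `spe`, `sen`
#' @export
scalar_metrics <- function(cc, two_class_mean = FALSE) {
  total <- cc$TP + cc$FP + cc$TN + cc$FN
  fg_absent <- (cc$TP + cc$FP + cc$FN) == 0
  bg_absent <- (cc$TN + cc$FN + cc$FP) == 0
  iou_fg <- safe_ratio(cc$TP, cc$TP + cc$FP + cc$FN, fg_absent)
  miou <- if (two_class_mean) {
    iou_bg <- safe_ratio(cc$TN, cc$TN + cc$FN + cc$FP, bg_absent)
    (iou_fg + iou_bg) / 2
  } else iou_fg
  list(
    miou = miou,
    dsc = safe_ratio(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN, fg_absent),
    acc = safe_ratio(cc$TP + cc$TN, total, total == 0),
    spe = safe_ratio(cc$TN, cc$TN + cc$FP, (cc$TN + cc$FP) == 0),
    sen = safe_ratio(cc$TP, cc$TP + cc$FN, (cc$TP + cc$FN) == 0)
  )
}

# boundary = foreground pixels with at least one background 4-neighbour
# (image border counts as background); returns an n x 2 matrix of (row, col)
boundary_pixels <- function(mask) {
  d <- dim(mask)
  H <- d[1]; W <- d[2]
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb_min <- pmin(pad[1:H, 2:(W + 1)], pad[3:(H + 2), 2:(W + 1)],
                 pad[2:(H + 1), 1:W], pad[2:(H + 1), 3:(W + 2)])
  b <- which(core == 1 & nb_min == 0, arr.ind = TRUE)
  storage.mode(b) <- "double"
  b
}

#' 95th-percentile symmetric Hausdorff boundary distance
#'
#' Distances are Euclidean between boundary pixel centres, where a boundary
#' pixel is a foreground pixel with a background 4-neighbour. The two
#' directed distances are the 95th percentiles of the nearest-neighbour
#' distances from one boundary set to the other; the result is their
#' maximum, scaled by `spacing`. If exactly one mask is empty the image
#' diagonal is returned; if both are empty, 0.
#'
#' @param pred,gt binary maps of equal shape
#' @param spacing pixel size in physical units
#' @return non-negative scalar
#' @export
hd95 <- function(pred, gt, spacing = 1) {
  if (!identical(dim(pred), dim(gt))) stop("hd95: shape mismatch")
  pe <- sum(pred) == 0
  ge <- sum(gt) == 0
  if (pe && ge) return(0)
  if (pe || ge) return(spacing * sqrt(sum((dim(gt) - 1)^2)))
  bp <- boundary_pixels(pred)
  bg <- boundary_pixels(gt)
  dxy <- stats::quantile(cpp_directed_dists(bp, bg), 0.95, names = FALSE)
  dyx <- stats::quantile(cpp_directed_dists(bg, bp), 0.95, names = FALSE)
  spacing * max(dxy, dyx)
}

#' Evaluate predictions against reference masks
#'
#' @param preds,gts lists of binary maps
#' @param ids optional image identifiers
#' @return data.frame with one row per image (id + 6 metrics) and one
#'   aggregate row (`id = "mean"`) holding column means
#' @export
evaluate_masks <- function(preds, gts, ids = NULL) {
  stopifnot(length(preds) == length(gts))
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    sm <- scalar_metrics(confusion(preds[[i]], gts[[i]]))
    data.frame(id = ids[i], miou = sm$miou, dsc = sm$dsc, acc = sm$acc,
               spe = sm$spe, sen = sm$sen, hd95 = hd95(preds[[i]], gts[[i]]))
  })
  df <- do.call(rbind, rows)
  agg <- data.frame(id = "mean", t(colMeans(df[, -1, drop = FALSE])))
  names(agg) <- names(df)
  rbind(df, agg)
}
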