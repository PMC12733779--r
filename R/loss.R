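# Deep-supervised BCE + Dice objective.
#
# Each of the five decoder stages emits a full-resolution logit map; the
# total loss is the stage-weighted sum of per-stage BCE + Dice terms.

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(y log p + (1-y) log(1-p))`, scaled by `lambda`.
#' Predictions are clamped to `[clamp, 1 - clamp]` before the logs.
#'
#' @param pred probability map in `(0, 1)` (clamped if on the boundary)
#' @param target binary map with the same shape
#' @param lambda loss weight
#' @param clamp clamping constant
#' @return scalar loss
#' @export
bce_loss <- function(pred, target, lambda = 1, clamp = 1e-7) {
  stopifnot(length(pred) == length(target))
  p <- pmin(pmax(pred, clamp), 1 - clamp)
  lambda * mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

#' Dice loss with Laplace smoothing
#'
#' `lambda * (1 - (2 |y  p| + eps) / (|y| + |p| + eps))`. With `epsilon = 1`
#' the loss is 0 when both masks are empty.
#'
#' @param pred probability map
#' @param target binary map with the same shape
#' @param lambda loss weight
#' @param epsilon smoothing constant in numerator and denominator
#' @return scalar loss
#' @export
dice_loss <- function(pred, target, lambda = 1, epsilon = 1) {
  stopifnot(length(pred) == length(target))
  num <- 2 * sum(pred * target) + epsilon
  den <- sum(pred) + sum(target) + epsilon
  lambda * (1 - num / den)
}

#' Deep-supervision total loss
#'
#' @param probs list of per-stage probability maps (all at target resolution)
#' @param target binary map
#' @param loss_cfg list with `lambda_bce`, `lambda_dice`, `stage_weights`,
#'   `epsilon` (see [default_config()]`$loss`)
#' @return scalar: sum over stages of `w_t * (BCE_t + Dice_t)`
#' @export
total_loss <- function(probs, target, loss_cfg = default_config()$loss) {
  if (length(loss_cfg$stage_weights) != length(probs))
    stop("total_loss: stage_weights length must match the number of stages")
  s <- 0
  for (t in seq_along(probs)) {
    w <- loss_cfg$stage_weights[t]
    if (w == 0) next
    s <- s + w * (bce_loss(probs[[t]], target, loss_cfg$lambda_bce) +
                    dice_loss(probs[[t]], target, loss_cfg$lambda_dice,
                              epsilon = loss_cfg$epsilon))
  }
  s
}

# Differentiable stage loss from logits (numerically stable BCE-with-logits).
stage_loss_ad <- function(z, target, loss_cfg) {
  yt <- ad_tensor(target)
  zz <- ad_reshape(z, dim(target))
  bce <- ad_mean(ad_sub(ad_softplus(zz), ad_mul(zz, yt)))
  p <- ad_sigmoid(zz)
  num <- ad_add(ad_scale(ad_sum(ad_mul(p, yt)), 2), loss_cfg$epsilon)
  den <- ad_add(ad_add(ad_sum(p), sum(target)), loss_cfg$epsilon)
  dice <- ad_sub(ad_tensor(1), ad_div(num, den))
  ad_add(ad_scale(bce, loss_cfg$lambda_bce), ad_scale(dice, loss_cfg$lambda_dice))
}

total_loss_ad <- function(logits, target, loss_cfg) {
  total <- NULL
  for (t in seq_along(logits)) {
    w <- loss_cfg$stage_weights[t]
    if (w == 0) next
    lt <- stage_loss_ad(logits[[t]], target, loss_cfg)
    lt <- if (w == 1) lt else ad_scale(lt, w)
    total <- if (is.null(total)) lt else ad_add(total, lt)
  }
  if (is.null(total)) ad_tensor(0) else total
}
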