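# Training: AdamW with a single-cycle cosine learning-rate schedule,
# flip/rotation augmentation, deep supervision, and evaluation.

adamw_new <- function(params) {
  st <- new.env(parent = emptyenv())
  st$step <- 0L
  st$m <- lapply(params, function(p) array(0, dim = c(length(ad_val(p)))))
  st$v <- lapply(params, function(p) array(0, dim = c(length(ad_val(p)))))
  st
}

adamw_step <- function(st, params, lr, betas = c(0.9, 0.999), eps = 1e-8,
                       weight_decay = 1e-2) {
  st$step <- st$step + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^st$step
  bc2 <- 1 - b2^st$step
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- as.vector(p$grad)
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    # decoupled weight decay
    p$v <- p$v - lr * (keep_dim(upd, p$v) + weight_decay * p$v)
  }
  invisible(st)
}

#' Cosine-annealed learning rate
#' @param epoch 0-based epoch index
#' @param base_lr initial learning rate
#' @param t_max half-period of the cosine cycle (epochs)
#' @param eta_min floor learning rate
#' @return learning rate for this epoch
#' @export
cosine_lr <- function(epoch, base_lr = 1e-3, t_max = 50, eta_min = 1e-5) {
  eta_min + 0.5 * (base_lr - eta_min) * (1 + cos(pi * (epoch %% (2 * t_max)) / t_max))
}

rotate_map <- function(m, angle_deg, nearest = FALSE, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  a <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- matrix(rep(seq_len(H), times = W), H, W) - cy
  cc <- matrix(rep(seq_len(W), each = H), H, W) - cx
  sr <- cos(a) * rr - sin(a) * cc + cy
  sc <- sin(a) * rr + cos(a) * cc + cx
  if (nearest) {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(fill, H, W)
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  out <- matrix(fill, H, W)
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- matrix(0, H, W)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  gv(r0, c0) * (1 - fr) * (1 - fc) + gv(r0 + 1, c0) * fr * (1 - fc) +
    gv(r0, c0 + 1) * (1 - fr) * fc + gv(r0 + 1, c0 + 1) * fr * fc
}

# identical geometric transform on image and mask; masks use nearest-neighbour
augment_pair <- function(image, mask, flip_prob = 0.5, max_rotation = 30) {
  if (stats::runif(1) < flip_prob) {   # horizontal flip
    image <- image[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (stats::runif(1) < flip_prob) {   # vertical flip
    image <- image[rev(seq_len(nrow(mask))), , , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  ang <- stats::runif(1, -max_rotation, max_rotation)
  if (abs(ang) > 1e-8) {
    for (ch in 1:3) image[, , ch] <- rotate_map(image[, , ch], ang)
    mask <- rotate_map(mask, ang, nearest = TRUE)
  }
  list(image = image, mask = mask)
}

# per-channel mean/sd computed on a list of (H, W, 3) images
channel_stats <- function(images) {
  means <- sapply(1:3, function(ch) mean(sapply(images, function(im) mean(im[, , ch]))))
  sds <- sapply(1:3, function(ch) {
    v <- unlist(lapply(images, function(im) as.vector(im[, , ch])))
    stats::sd(v)
  })
  sds[sds < 1e-6] <- 1
  list(mean = means, sd = sds)
}

normalize_image <- function(image, st) {
  for (ch in 1:3) image[, , ch] <- (image[, , ch] - st$mean[ch]) / st$sd[ch]
  image
}

# One optimizer step on a batch. Returns the mean total loss and the mean
# training DSC, both measured on the training-mode forward before the step.
train_batch <- function(m, opt, images, masks, lr, tcfg) {
  ad_zero_grad(m$params)
  nb <- length(images)
  tot <- 0
  dscs <- numeric(nb)
  for (i in seq_len(nb)) {
    out <- net_forward(m, ad_tensor(images[[i]]), training = TRUE)
    loss <- total_loss_ad(out$logits, masks[[i]], m$cfg$loss)
    tot <- tot + ad_val(loss)
    pm <- (ad_val(out$logits[[1]])[, , 1] >= 0) * 1   # sigmoid(z) >= 0.5
    dscs[i] <- scalar_metrics(confusion(pm, masks[[i]]))$dsc
    ad_backward(loss)
  }
  for (p in m$params) if (!is.null(p$grad)) p$grad <- p$grad / nb
  adamw_step(opt, m$params, lr, tcfg$betas, tcfg$eps, tcfg$weight_decay)
  list(loss = tot / nb, dsc = mean(dscs))
}

#' Train a segmentation network
#'
#' AdamW + cosine schedule with deep supervision. When `val_frac > 0` an
#' 80/20-style sub-split of the training images selects the best epoch by
#' validation DSC; the returned model carries the best weights.
#'
#' @param m a `segnet` (modified in place)
#' @param images,masks training data: lists of (H, W, 3) arrays in `[0, 1]`
#'   and binary matrices
#' @param train_config see [default_train_config()]
#' @param steps optional cap on total optimizer steps (overrides epochs)
#' @param augment apply flip/rotation augmentation?
#' @param checkpoint optional path: best weights are saved there
#' @param log_file optional path for a per-epoch log
#' @param verbose print per-epoch progress?
#' @return list with `history` (data.frame of epoch, lr, loss, val_dsc) and
#'   `norm` (channel statistics used to normalize inputs)
#' @export
fit_segnet <- function(m, images, masks, train_config = default_train_config(),
                       steps = NULL, augment = TRUE, checkpoint = NULL,
                       log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(m, "segnet"), length(images) == length(masks))
  tcfg <- train_config
  set.seed(tcfg$seed)
  n <- length(images)
  n_val <- if (tcfg$val_frac > 0 && n >= 5) max(1L, round(tcfg$val_frac * n)) else 0L
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  norm <- channel_stats(images[tr_idx])
  images_n <- lapply(images, normalize_image, st = norm)
  opt <- adamw_new(m$params)
  best_dsc <- -Inf
  best <- NULL
  hist <- list()
  done <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    lr <- cosine_lr(epoch - 1L, tcfg$lr, tcfg$cosine_t_max, tcfg$eta_min)
    ord <- sample(tr_idx)
    ep_loss <- 0; nb <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / tcfg$batch_size))) {
      bi <- images_n[b]; bm <- masks[b]
      if (augment) {
        for (j in seq_along(b)) {
          au <- augment_pair(bi[[j]], bm[[j]], tcfg$flip_prob, tcfg$max_rotation)
          bi[[j]] <- au$image; bm[[j]] <- au$mask
        }
      }
      ep_loss <- ep_loss + train_batch(m, opt, bi, bm, lr, tcfg)$loss
      nb <- nb + 1L
      done <- done + 1L
      if (!is.null(steps) && done >= steps) break
    }
    val_dsc <- NA_real_
    if (n_val > 0) {
      dscs <- vapply(val_idx, function(i) {
        pr <- ad_no_grad(net_forward(m, ad_tensor(images_n[[i]])))
        pm <- (1 / (1 + exp(-ad_val(pr$logits[[1]])[, , 1])) >= 0.5) * 1
        scalar_metrics(confusion(pm, masks[[i]]))$dsc
      }, numeric(1))
      val_dsc <- mean(dscs)
      if (val_dsc >= best_dsc) {
        best_dsc <- val_dsc
        best <- lapply(m$params, ad_val)
        if (!is.null(checkpoint)) save_checkpoint(m, checkpoint)
      }
    } else if (!is.null(checkpoint)) {
      save_checkpoint(m, checkpoint)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr, loss = ep_loss / max(nb, 1L),
                                val_dsc = val_dsc)
    line <- sprintf("epoch %d lr %.2e loss %.4f val_dsc %s", epoch, lr,
                    ep_loss / max(nb, 1L),
                    ifelse(is.na(val_dsc), "NA", sprintf("%.4f", val_dsc)))
    if (verbose) message(line)
    if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
    if (!is.null(steps) && done >= steps) break
  }
  if (!is.null(best)) for (nm in names(best)) m$params[[nm]]$v <- best[[nm]]
  list(history = do.call(rbind, hist), norm = norm)
}

#' Evaluate a model on a dataset
#'
#' @param m a `segnet`
#' @param images,masks lists as in [fit_segnet()]
#' @param norm channel statistics from training (NULL for none)
#' @param ids optional image identifiers
#' @return per-image + aggregate metric data.frame from [evaluate_masks()]
#' @export
evaluate_segnet <- function(m, images, masks, norm = NULL, ids = NULL) {
  preds <- lapply(images, function(im) {
    if (!is.null(norm)) im <- normalize_image(im, norm)
    segnet_predict(m, im)$mask
  })
  evaluate_masks(preds, masks, ids)
}
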