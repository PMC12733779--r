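# Network assembly: 5-stage prompt encoder, 5-stage attention decoder,
# 4 cross-attention fusions and 5 deeply supervised segmentation heads.
#
# The stage schedule for a 256x256 input is (8,256,256), (16,128,128),
# (24,64,64), (32,32,32), (40,16,16): channels C_i = 8*i, resolution halved
# from stage 2 on. The network is fully convolutional, so any input side
# divisible by 16 is accepted; the printed schedule corresponds to 256.

add_head <- function(P, t, C, hidden) {
  pre <- paste0("head", t)
  P <- add_conv(P, paste0(pre, ".fc1"), 1L, C, hidden)
  add_conv(P, paste0(pre, ".fc2"), 1L, hidden, 1L)
}

head_fw <- function(P, t, x, cfg) {
  pre <- paste0("head", t)
  conv_fw(P, paste0(pre, ".fc2"),
          eta_fw(conv_fw(P, paste0(pre, ".fc1"), x, 1L), cfg$eta), 1L)
}

#' Create a segmentation network
#'
#' Instantiates the full encoder-decoder network from a configuration.
#' Weights are initialized reproducibly from `config$seed`.
#'
#' @param config model configuration, see [default_config()]
#' @return object of class `segnet`: parameters, normalization buffers and
#'   the config
#' @export
new_segnet <- function(config = default_config()) {
  cfg <- config
  set.seed(cfg$seed)
  P <- list()
  cin <- cfg$in_channels
  for (t in 1:5) {
    P <- add_pcm_stage(P, t, cin, cfg$stage_channels[t], cfg)
    cin <- cfg$stage_channels[t]
  }
  for (t in 1:5) P <- add_mca_stage(P, t, cfg$stage_channels[t], cfg)
  if (cfg$use_caf)
    for (t in 1:4) P <- add_caf_stage(P, t, cfg$stage_channels[t],
                                      cfg$stage_channels[t + 1])
  for (t in 1:5) P <- add_head(P, t, cfg$stage_channels[t], cfg$head_hidden[t])
  m <- new.env(parent = emptyenv())
  m$params <- P
  m$buf <- new.env(parent = emptyenv())
  m$cfg <- cfg
  class(m) <- "segnet"
  m
}

# Full forward pass on tensors. Returns the five per-stage logit maps,
# upsampled to the input resolution, plus intermediate stage features.
net_forward <- function(m, x, training = FALSE, keep_stages = FALSE) {
  cfg <- m$cfg
  P <- m$params
  d <- dim(ad_val(x))
  if (d[3] != cfg$in_channels)
    stop("forward: input must have ", cfg$in_channels, " channels")
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("forward: input sides must be divisible by 16")
  enc <- vector("list", 5L)
  h <- x
  for (t in 1:5) {
    st <- pcm_stage_fw(P, t, h, cfg, m$buf, training)
    enc[[t]] <- st
    h <- st$f_pt
  }
  dec <- vector("list", 5L)
  dec[[5]] <- mca_stage_fw(P, 5L, enc[[5]]$f_pt, cfg, m$buf, training)
  for (t in 4:1) {
    fin <- if (cfg$use_caf)
      caf_stage_fw(P, t, dec[[t + 1]], enc[[t]]$f_pt, cfg, m$buf, training)
    else enc[[t]]$f_pt
    dec[[t]] <- mca_stage_fw(P, t, fin, cfg, m$buf, training)
  }
  logits <- vector("list", 5L)
  for (t in 1:5) {
    z <- head_fw(P, t, dec[[t]], cfg)
    dz <- dim(ad_val(z))
    logits[[t]] <- if (dz[1] == d[1] && dz[2] == d[2]) z
                   else ad_upsample(z, d[1], d[2])
  }
  out <- list(logits = logits)
  if (keep_stages) { out$enc <- enc; out$dec <- dec }
  out
}

#' Run the network on one image
#'
#' @param m a `segnet`
#' @param image numeric array (H, W, 3) with values in `[0, 1]` or already
#'   normalized; sides must be divisible by 16
#' @param stages also return encoder/decoder stage features and prompts?
#' @return list with `prob` (H x W probability map from the stage-1 head),
#'   `mask` (binary at threshold 0.5) and `logits` (list of 5 H x W maps)
#' @export
segnet_predict <- function(m, image, stages = FALSE) {
  stopifnot(inherits(m, "segnet"))
  out <- ad_no_grad(net_forward(m, ad_tensor(image), training = FALSE,
                                keep_stages = stages))
  logits <- lapply(out$logits, function(z) ad_val(z)[, , 1])
  prob <- 1 / (1 + exp(-logits[[1]]))
  res <- list(prob = prob, mask = (prob >= 0.5) * 1, logits = logits)
  if (stages) {
    res$prompts <- lapply(out$enc, function(s)
      list(p1 = if (!is.null(s$p1)) ad_val(s$p1)[, , 1],
           p2 = if (!is.null(s$p2)) ad_val(s$p2)[, , 1]))
    res$stage_shapes <- lapply(out$enc, function(s) dim(ad_val(s$f_pt)))
  }
  res
}

#' Flat list of trainable parameter tensors
#' @param m a `segnet`
#' @return named list of `ad_tensor`
#' @export
segnet_params <- function(m) m$params

#' Save a checkpoint (weights + normalization buffers + config)
#' @param m a `segnet`
#' @param path file to write (RDS)
#' @export
save_checkpoint <- function(m, path) {
  saveRDS(list(values = lapply(m$params, ad_val),
               buffers = as.list(m$buf),
               config = m$cfg), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file
#' @return a `segnet`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- new_segnet(ck$config)
  stopifnot(identical(sort(names(ck$values)), sort(names(m$params))))
  for (nm in names(ck$values)) m$params[[nm]]$v <- ck$values[[nm]]
  for (nm in names(ck$buffers)) m$buf[[nm]] <- ck$buffers[[nm]]
  m
}
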