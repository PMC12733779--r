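# Context-enhanced decoder stage (MCA) with the EASC gate chain.
#
# Each stage: vision-Mamba pre-pass; four parallel depthwise-separable
# convolutions (kernels 3/5/7/9, each mapping C -> C/4) concatenated back to
# C channels; a 3x3 depthwise + pointwise context embedding with BN; then
# edge-enhancement, spatial-attention and channel-attention gates, each a
# sigmoid score multiplying the features plus an additive residual; finally
# a skip connection back onto the Mamba output.

add_mca_stage <- function(P, t, C, cfg) {
  pre <- paste0("dec", t)
  if (C %% 4L != 0L) stop("MCA channels must be divisible by 4")
  P <- add_vm_block(P, paste0(pre, ".vm"), C, stage_mcfg(cfg$dec_mamba, t))
  for (i in 1:4) {
    k <- cfg$branch_kernels[i]
    P <- add_conv(P, paste0(pre, ".br", i, ".dw"), k, C, C, groups = C)
    P <- add_conv(P, paste0(pre, ".br", i, ".pw"), 1L, C, C %/% 4L)
  }
  P <- add_conv(P, paste0(pre, ".ce.dw"), 3L, C, C, groups = C)
  P <- add_conv(P, paste0(pre, ".ce.pw"), 1L, C, C)
  P <- add_norm(P, paste0(pre, ".ce.bn"), C)
  if (cfg$use_ee) {
    P <- add_conv(P, paste0(pre, ".ee.dw"), 7L, C, C, groups = C)
    P <- add_norm(P, paste0(pre, ".ee.bn"), C)
    P <- add_conv(P, paste0(pre, ".ee.pw"), 1L, C, 1L)
  }
  if (cfg$use_sa) {
    P <- add_conv(P, paste0(pre, ".sa.dw1"), 7L, C, C, groups = C)
    P <- add_norm(P, paste0(pre, ".sa.bn1"), C)
    P <- add_conv(P, paste0(pre, ".sa.dw2"), 3L, C, C, groups = C)
    P <- add_norm(P, paste0(pre, ".sa.bn2"), C)
    P <- add_conv(P, paste0(pre, ".sa.pw"), 1L, C, 1L)
  }
  if (cfg$use_ca) {
    P <- add_conv(P, paste0(pre, ".ca.fc1"), 1L, C, C)
    P <- add_conv(P, paste0(pre, ".ca.fc2"), 1L, C, C)
  }
  P
}

# four-branch multi-scale depthwise separable convolutions, concat to C
multiscale_fw <- function(P, pre, x, cfg) {
  C <- dim(ad_val(x))[3]
  xs <- vector("list", 4L)
  for (i in 1:4) {
    h <- conv_fw(P, paste0(pre, ".br", i, ".dw"), x, cfg$branch_kernels[i],
                 groups = C)
    xs[[i]] <- conv_fw(P, paste0(pre, ".br", i, ".pw"), h, 1L)
  }
  ad_concat_ch(xs)
}

context_embed_fw <- function(P, pre, x, buf, training) {
  C <- dim(ad_val(x))[3]
  h <- conv_fw(P, paste0(pre, ".ce.dw"), x, 3L, groups = C)
  h <- conv_fw(P, paste0(pre, ".ce.pw"), h, 1L)
  bn_fw(P, paste0(pre, ".ce.bn"), h, buf, training)
}

# edge gate: xbar = BN(x - AvgPool3(DWConv7(x))); sigmoid(pw(xbar)) * x + x
ee_fw <- function(P, pre, x, buf, training) {
  C <- dim(ad_val(x))[3]
  sm <- ad_avgpool3(conv_fw(P, paste0(pre, ".ee.dw"), x, 7L, groups = C))
  xbar <- bn_fw(P, paste0(pre, ".ee.bn"), ad_sub(x, sm), buf, training)
  gate <- ad_sigmoid(conv_fw(P, paste0(pre, ".ee.pw"), xbar, 1L))
  ad_add(ad_mul_bcast(x, gate), x)
}

# spatial gate: 7x7 dw -> 3x3 dw -> pointwise-to-1, sigmoid(eta(.)) * x + x
sa_fw <- function(P, pre, x, cfg, buf, training) {
  C <- dim(ad_val(x))[3]
  s1 <- bn_fw(P, paste0(pre, ".sa.bn1"),
              conv_fw(P, paste0(pre, ".sa.dw1"), x, 7L, groups = C),
              buf, training)
  s2 <- bn_fw(P, paste0(pre, ".sa.bn2"),
              conv_fw(P, paste0(pre, ".sa.dw2"), s1, 3L, groups = C),
              buf, training)
  gate <- ad_sigmoid(eta_fw(conv_fw(P, paste0(pre, ".sa.pw"), s2, 1L), cfg$eta))
  ad_add(ad_mul_bcast(x, gate), x)
}

# channel gate: global max pool -> pw -> ReLU -> pw -> sigmoid, broadcast
ca_fw <- function(P, pre, x) {
  w <- ad_relu(conv_fw(P, paste0(pre, ".ca.fc1"), ad_global_maxpool(x), 1L))
  gate <- ad_sigmoid(conv_fw(P, paste0(pre, ".ca.fc2"), w, 1L))
  ad_add(ad_mul_chan(x, gate), x)
}

mca_stage_fw <- function(P, t, x, cfg, buf, training) {
  pre <- paste0("dec", t)
  f_vmt <- vm_block_fw(P, paste0(pre, ".vm"), x, stage_mcfg(cfg$dec_mamba, t))
  f <- multiscale_fw(P, pre, f_vmt, cfg)
  f <- context_embed_fw(P, pre, f, buf, training)
  if (cfg$use_ee) f <- ee_fw(P, pre, f, buf, training)
  if (cfg$use_sa) f <- sa_fw(P, pre, f, cfg, buf, training)
  if (cfg$use_ca) f <- ca_fw(P, pre, f)
  ad_add(f, f_vmt)
}
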