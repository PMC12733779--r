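# Context prompt encoder stage (PCM).
#
# Each stage runs an inverted-pyramid convolution (large-kernel depthwise
# separable conv with the stage stride, then a small-kernel depthwise conv,
# then a pointwise aggregation), a vision-Mamba global path, fuses the two
# with weights (lambda1, lambda2) through a pointwise conv, and derives two
# self-prompt masks: p1 from the convolutional features (BN + sigmoid) and
# p2 from the Mamba features (LN + sigmoid). The prompts are added back onto
# the fused features, broadcast across channels.

add_pcm_stage <- function(P, t, cin, cout, cfg) {
  pre <- paste0("enc", t)
  P <- add_conv(P, paste0(pre, ".ipc.dwl"), cfg$large_kernel, cin, cin, groups = cin)
  P <- add_conv(P, paste0(pre, ".ipc.pw1"), 1L, cin, cout)
  P <- add_conv(P, paste0(pre, ".ipc.dws"), cfg$small_kernel, cout, cout, groups = cout)
  P <- add_conv(P, paste0(pre, ".ipc.pw2"), 1L, cout, cout)
  if (cfg$use_mamba_in_pcm)
    P <- add_vm_block(P, paste0(pre, ".vm"), cout, stage_mcfg(cfg$enc_mamba, t))
  P <- add_conv(P, paste0(pre, ".fuse"), 1L, cout, cout)
  if (cfg$use_prompts) {
    P <- add_conv(P, paste0(pre, ".p1"), 1L, cout, 1L)
    P <- add_norm(P, paste0(pre, ".p1bn"), 1L)
    P <- add_conv(P, paste0(pre, ".p2"), 1L, cout, 1L)
    P <- add_norm(P, paste0(pre, ".p2ln"), 1L)
  }
  P
}

# coarse-to-fine convolutional path; spatial dims divide by the stage stride
ipc_fw <- function(P, pre, x, cfg, stride) {
  cin <- dim(ad_val(x))[3]
  cout <- length(ad_val(P[[paste0(pre, ".ipc.pw1.b")]]))
  h <- conv_fw(P, paste0(pre, ".ipc.dwl"), x, cfg$large_kernel,
               stride = stride, groups = cin)
  h <- eta_fw(conv_fw(P, paste0(pre, ".ipc.pw1"), h, 1L), cfg$eta)
  h <- eta_fw(conv_fw(P, paste0(pre, ".ipc.dws"), h, cfg$small_kernel,
                      groups = cout), cfg$eta)
  conv_fw(P, paste0(pre, ".ipc.pw2"), h, 1L)
}

pcm_stage_fw <- function(P, t, x, cfg, buf, training) {
  pre <- paste0("enc", t)
  f_ipc <- ipc_fw(P, pre, x, cfg, cfg$stage_strides[t])
  lam1 <- if (cfg$use_mamba_in_pcm) cfg$lambda1 else 0
  f_m <- if (cfg$use_mamba_in_pcm)
    vm_block_fw(P, paste0(pre, ".vm"), f_ipc, stage_mcfg(cfg$enc_mamba, t),
                v1 = 1, v2 = 0)
  else f_ipc
  mix <- if (lam1 > 0) ad_add(ad_scale(f_m, lam1), ad_scale(f_ipc, cfg$lambda2))
         else ad_scale(f_ipc, cfg$lambda2)
  f_et <- conv_fw(P, paste0(pre, ".fuse"), mix, 1L)
  p1 <- NULL; p2 <- NULL
  f_pt <- f_et
  if (cfg$use_prompts) {
    p1 <- ad_sigmoid(bn_fw(P, paste0(pre, ".p1bn"),
                           conv_fw(P, paste0(pre, ".p1"), f_ipc, 1L),
                           buf, training))
    p2 <- ad_sigmoid(ad_layernorm_all(conv_fw(P, paste0(pre, ".p2"), f_m, 1L),
                                      P[[paste0(pre, ".p2ln.g")]],
                                      P[[paste0(pre, ".p2ln.b")]]))
    if (cfg$prompt_lambda1 != 0)
      f_pt <- ad_add_bcast(f_pt, if (cfg$prompt_lambda1 == 1) p1
                                 else ad_scale(p1, cfg$prompt_lambda1))
    if (cfg$prompt_lambda2 != 0)
      f_pt <- ad_add_bcast(f_pt, if (cfg$prompt_lambda2 == 1) p2
                                 else ad_scale(p2, cfg$prompt_lambda2))
  }
  list(f_pt = f_pt, f_m = f_m, f_ipc = f_ipc, f_et = f_et, p1 = p1, p2 = p2)
}
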