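# Cross-attention fusion (CAF).
#
# Fuses the next-deeper decoder output (semantic guidance) with the
# same-stage encoder output (texture detail). The deep feature is upsampled
# x2 and projected to the stage's channel count as the query Q; the encoder
# feature is projected as the key K. Both are flattened to C x N token
# matrices; the affinity Q K^T is C x C (linear in N), softmax-normalized by
# tau = sqrt(N), and applied to two values: V1 = Q and V2 = the flattened
# encoder feature. The sum of the two attention outputs is reshaped and
# passed through a pointwise conv + activation.

add_caf_stage <- function(P, t, C, Cnext) {
  pre <- paste0("caf", t)
  P <- add_conv(P, paste0(pre, ".q"), 1L, Cnext, C)
  P <- add_norm(P, paste0(pre, ".qbn"), C)
  P <- add_conv(P, paste0(pre, ".k"), 1L, C, C)
  P <- add_norm(P, paste0(pre, ".kbn"), C)
  add_conv(P, paste0(pre, ".o"), 1L, C, C)
}

# row-stochastic attention weights softmax((Q K^T) / tau); C x C
attention_weights_ad <- function(Q, K, tau) {
  aff <- ad_scale(ad_matmul(Q, ad_op(t(ad_val(K)), list(K),
                                     function(g) list(t(g)))), 1 / tau)
  if (!all(is.finite(ad_val(aff)))) stop("scaled attention: non-finite affinities")
  ad_softmax_rows(aff)
}

caf_stage_fw <- function(P, t, f_m_next, f_pt, cfg, buf, training) {
  pre <- paste0("caf", t)
  de <- dim(ad_val(f_pt))
  dn <- dim(ad_val(f_m_next))
  if (de[1] != 2L * dn[1] || de[2] != 2L * dn[2])
    stop("CAF: decoder feature must be exactly twice coarser than encoder feature")
  H <- de[1]; W <- de[2]
  up <- ad_upsample(f_m_next, H, W)
  qmap <- bn_fw(P, paste0(pre, ".qbn"), conv_fw(P, paste0(pre, ".q"), up, 1L),
                buf, training)
  kmap <- bn_fw(P, paste0(pre, ".kbn"), conv_fw(P, paste0(pre, ".k"), f_pt, 1L),
                buf, training)
  Q <- ad_tokens(qmap)
  K <- ad_tokens(kmap)
  V2 <- ad_tokens(f_pt)
  tau <- sqrt(H * W)
  Wm <- attention_weights_ad(Q, K, tau)
  fa <- ad_add(ad_matmul(Wm, Q), ad_matmul(Wm, V2))
  eta_fw(conv_fw(P, paste0(pre, ".o"), ad_untokens(fa, H, W), 1L), cfg$eta)
}

#' Row-stochastic scaled attention
#'
#' Computes `softmax(Q K^T / tau) V` with the affinity taken over the channel
#' axis (C x C), so cost is linear in the token count N.
#'
#' @param Q,K (C x N) token matrices
#' @param V (C x N) value matrix
#' @param tau positive normalization factor; defaults to `sqrt(ncol(Q))`
#' @return (C x N) matrix
#' @export
scaled_attention <- function(Q, K, V, tau = sqrt(ncol(Q))) {
  stopifnot(tau > 0, ncol(Q) == ncol(K), ncol(K) == ncol(V))
  aff <- Q %*% t(K) / tau
  if (!all(is.finite(aff))) stop("scaled_attention: non-finite affinities")
  mx <- apply(aff, 1, max)
  e <- exp(aff - mx)
  (e / rowSums(e)) %*% V
}
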