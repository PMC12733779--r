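# Analytic parameter and FLOP accounting.
#
# Parameter counts are exact (they equal the number of trainable scalars in
# the instantiated model; a test enforces this). FLOPs follow the
# multiply-accumulate convention of the common network profilers:
#   * conv (k, cin, cout, groups) at N output positions:
#       k^2 * cin/groups * cout * N MACs (bias excluded)
#   * dense (rout x rin) applied to L tokens: rout * rin * L
#   * selective scan, per direction, per token: 6*E*d + 2*E
#     (discretization exp+mult, state update, output projection, skip)
#   * attention at C channels / N tokens: 3 * C^2 * N
#     (one C x C affinity + the weight matrix applied to both value branches)
#   * normalizations, activations, pooling and interpolation are not counted
# 1 MAC = 1 FLOP; totals are reported in M (1e6) parameters and G (1e9) FLOPs.

conv_cost <- function(k, cin, cout, N, groups = 1) {
  c(params = k^2 * (cin / groups) * cout + cout,
    flops = k^2 * (cin / groups) * cout * N)
}

dense_cost <- function(rin, rout, L, bias = FALSE) {
  c(params = rin * rout + if (bias) rout else 0, flops = rin * rout * L)
}

vm_cost <- function(C, mcfg, N) {
  E <- round(mcfg$expand * C)
  d <- mcfg$d_state
  r <- mcfg$dt_rank
  p <- 2 * C                                  # pre-LN
  f <- 0
  cc <- conv_cost(1, C, E, N); p <- p + cc["params"]; f <- f + cc["flops"]
  if (isTRUE(mcfg$conv_branch)) {
    cc <- conv_cost(3, E, E, N, groups = E); p <- p + cc["params"]; f <- f + cc["flops"]
  }
  for (k in 1:4) {
    cc <- dense_cost(E, r + 2 * d, N); p <- p + cc["params"]; f <- f + cc["flops"]
    cc <- dense_cost(r, E, N); p <- p + cc["params"] + E; f <- f + cc["flops"]
    p <- p + E * d + E                        # A_log, D
    f <- f + N * (6 * E * d + 2 * E)          # the scan itself
  }
  p <- p + 2 * E                              # out-LN
  cc <- conv_cost(1, E, C, N); p <- p + cc["params"]; f <- f + cc["flops"]
  c(params = unname(p), flops = unname(f))
}

pcm_cost <- function(cin, C, t, cfg, N) {
  p <- 0; f <- 0
  add <- function(cc) { p <<- p + cc["params"]; f <<- f + cc["flops"] }
  add(conv_cost(cfg$large_kernel, cin, cin, N, groups = cin))
  add(conv_cost(1, cin, C, N))
  add(conv_cost(cfg$small_kernel, C, C, N, groups = C))
  add(conv_cost(1, C, C, N))
  if (cfg$use_mamba_in_pcm) {
    vc <- vm_cost(C, stage_mcfg(cfg$enc_mamba, t), N)
    p <- p + vc["params"]; f <- f + vc["flops"]
  }
  add(conv_cost(1, C, C, N))                  # fusion pointwise
  if (cfg$use_prompts) {
    add(conv_cost(1, C, 1, N)); p <- p + 2    # p1 + BN(1)
    add(conv_cost(1, C, 1, N)); p <- p + 2    # p2 + LN
  }
  c(params = unname(p), flops = unname(f))
}

mca_cost <- function(C, t, cfg, N) {
  vc <- vm_cost(C, stage_mcfg(cfg$dec_mamba, t), N)
  p <- vc["params"]; f <- vc["flops"]
  add <- function(cc) { p <<- p + cc["params"]; f <<- f + cc["flops"] }
  for (k in cfg$branch_kernels) {
    add(conv_cost(k, C, C, N, groups = C))
    add(conv_cost(1, C, C / 4, N))
  }
  add(conv_cost(3, C, C, N, groups = C))      # context embed
  add(conv_cost(1, C, C, N)); p <- p + 2 * C
  if (cfg$use_ee) {
    add(conv_cost(7, C, C, N, groups = C)); p <- p + 2 * C
    add(conv_cost(1, C, 1, N))
  }
  if (cfg$use_sa) {
    add(conv_cost(7, C, C, N, groups = C)); p <- p + 2 * C
    add(conv_cost(3, C, C, N, groups = C)); p <- p + 2 * C
    add(conv_cost(1, C, 1, N))
  }
  if (cfg$use_ca) {
    add(conv_cost(1, C, C, 1))
    add(conv_cost(1, C, C, 1))
  }
  c(params = unname(p), flops = unname(f))
}

caf_cost <- function(C, Cnext, N) {
  p <- 0; f <- 0
  add <- function(cc) { p <<- p + cc["params"]; f <<- f + cc["flops"] }
  add(conv_cost(1, Cnext, C, N)); p <- p + 2 * C   # Q proj + BN
  add(conv_cost(1, C, C, N)); p <- p + 2 * C       # K proj + BN
  f <- f + 3 * C^2 * N                             # affinity + two values
  add(conv_cost(1, C, C, N))                       # output pointwise
  c(params = unname(p), flops = unname(f))
}

head_cost <- function(C, hidden, N) {
  cc1 <- conv_cost(1, C, hidden, N)
  cc2 <- conv_cost(1, hidden, 1, N)
  c(params = unname(cc1["params"] + cc2["params"]),
    flops = unname(cc1["flops"] + cc2["flops"]))
}

#' Parameter and FLOP budget of a configuration
#'
#' Computes exact trainable-parameter counts and analytic forward-pass FLOPs
#' (multiply-accumulate convention, see the package vignette) at the
#' configured input size, partitioned into encoder (the prompt-encoder
#' stack), decoder (attention decoder stages plus cross-attention fusion)
#' and segmentation heads.
#'
#' @param cfg model configuration from [default_config()]
#' @return nested list: per component and total, `params` / `flops` (raw
#'   counts) and `params_M` / `flops_G` (scaled)
#' @export
count_budget <- function(cfg = default_config()) {
  S <- cfg$input_size
  sizes <- S / 2^(pmax(seq_len(5) - 1, 0))
  N <- sizes^2
  enc <- c(params = 0, flops = 0)
  cin <- cfg$in_channels
  for (t in 1:5) {
    enc <- enc + pcm_cost(cin, cfg$stage_channels[t], t, cfg, N[t])
    cin <- cfg$stage_channels[t]
  }
  dec <- c(params = 0, flops = 0)
  for (t in 1:5) dec <- dec + mca_cost(cfg$stage_channels[t], t, cfg, N[t])
  if (cfg$use_caf)
    for (t in 1:4)
      dec <- dec + caf_cost(cfg$stage_channels[t], cfg$stage_channels[t + 1], N[t])
  hd <- c(params = 0, flops = 0)
  for (t in 1:5) hd <- hd + head_cost(cfg$stage_channels[t], cfg$head_hidden[t], N[t])
  tot <- enc + dec + hd
  wrap <- function(x) list(params = unname(x["params"]), flops = unname(x["flops"]),
                           params_M = unname(x["params"]) / 1e6,
                           flops_G = unname(x["flops"]) / 1e9)
  list(encoder = wrap(enc), decoder = wrap(dec), heads = wrap(hd), total = wrap(tot))
}

#' Trainable parameter counts of an instantiated model, by component
#'
#' @param m a `segnet`
#' @return named numeric vector: encoder, decoder, heads, total
#' @export
param_counts <- function(m) {
  n <- vapply(m$params, function(p) length(ad_val(p)), numeric(1))
  nm <- names(m$params)
  enc <- sum(n[startsWith(nm, "enc")])
  dec <- sum(n[startsWith(nm, "dec") | startsWith(nm, "caf")])
  hd <- sum(n[startsWith(nm, "head")])
  c(encoder = enc, decoder = dec, heads = hd, total = enc + dec + hd)
}
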