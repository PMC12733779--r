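# Two-dimensional selective scan (SS2D): cross-scan expansion of a feature
# map along four directional paths, a selective state-space (S6) recurrence
# on each path, and a scan-merge back onto the grid. The vision-Mamba block
# wraps the SS2D core in channel layer-norm, input/output pointwise
# projections and a weighted residual.
#
# Feature maps are (H, W, C) arrays; token sequences are (C x L) matrices.

#' Scan-direction permutations
#'
#' Returns, for each of the four scan directions, the permutation mapping
#' sequence index to column-major grid index. `col_fwd` walks top-to-bottom
#' then left-to-right (the column-major order itself); `row_fwd` walks
#' left-to-right then top-to-bottom; the backward variants are exact
#' reversals. Each permutation is a bijection, so scan expansion loses
#' nothing and scan merging can invert it exactly.
#'
#' @param H,W grid height and width
#' @return named list of integer vectors (`row_fwd`, `row_bwd`, `col_fwd`,
#'   `col_bwd`), each of length `H * W`
#' @export
scan_perms <- function(H, W) {
  stopifnot(H >= 1, W >= 1)
  L <- H * W
  col_fwd <- seq_len(L)
  row_fwd <- as.vector(t(matrix(col_fwd, H, W)))
  list(row_fwd = row_fwd, row_bwd = rev(row_fwd),
       col_fwd = col_fwd, col_bwd = rev(col_fwd))
}

#' Cross-scan a feature map into four directional token sequences
#'
#' @param x numeric array (H, W, C)
#' @return named list of four (C x H*W) matrices, one per scan direction;
#'   each is a per-channel permutation of the entries of `x`
#' @export
cross_scan <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("cross_scan: x must be an (H, W, C) array")
  if (d[1] < 1 || d[2] < 1) stop("cross_scan: empty spatial dimensions")
  if (!all(is.finite(x))) stop("cross_scan: non-finite values in x")
  perms <- scan_perms(d[1], d[2])
  base <- matrix(x, d[1] * d[2], d[3])
  lapply(perms, function(p) t(base[p, , drop = FALSE]))
}

#' Merge four directional token sequences back onto the grid
#'
#' Each sequence is mapped back to its grid positions by inverting the
#' direction's bijection, and the four placements are summed elementwise.
#'
#' @param ys list of four (C x H*W) matrices in `scan_perms()` order
#' @param H,W grid height and width
#' @return numeric array (H, W, C)
#' @export
scan_merge <- function(ys, H, W) {
  stopifnot(length(ys) == 4L)
  L <- H * W
  C <- nrow(ys[[1]])
  for (y in ys) if (ncol(y) != L) stop("scan_merge: sequence length must equal H*W")
  perms <- scan_perms(H, W)
  acc <- matrix(0, L, C)
  for (k in 1:4) acc[perms[[k]], ] <- acc[perms[[k]], ] + t(ys[[k]])
  array(acc, dim = c(H, W, C))
}

#' Selective state-space scan (S6 recurrence)
#'
#' Runs the zero-order-hold discretized recurrence
#' \deqn{h_t = e^{\Delta_t A} h_{t-1} + \frac{e^{\Delta_t A} - 1}{A} B_t x_t,
#'       \quad y_t = C_t h_t + D x_t}
#' with h_0 = 0, independently per channel. The step size, input and output
#' projections vary per token, which is what makes the scan selective. As
#' \eqn{\Delta_t \to 0} the decay tends to the identity and the input gain
#' to zero, so \eqn{y_t \to D x_t}.
#'
#' @param x (E x L) input sequence, one column per token
#' @param delta (E x L) positive step sizes
#' @param A (E x d) state decay matrix, elementwise negative for stability
#' @param B,Cm (d x L) per-token input/output projections
#' @param D length-E skip coefficients
#' @return (E x L) output sequence
#' @export
selective_scan <- function(x, delta, A, B, Cm, D) {
  x <- as.matrix(x); delta <- as.matrix(delta); A <- as.matrix(A)
  B <- as.matrix(B); Cm <- as.matrix(Cm); D <- as.numeric(D)
  if (!all(is.finite(A)) || !all(is.finite(B)) || !all(is.finite(Cm)) ||
      !all(is.finite(D)) || !all(is.finite(delta)))
    stop("selective_scan: non-finite parameter values")
  if (any(delta <= 0)) stop("selective_scan: delta must be positive")
  cpp_selscan_fw(x, delta, A, B, Cm, D, FALSE)$y
}

# ---- vision-Mamba block --------------------------------------------------

# Parameters of one block under `prefix`, channels C, SS2D hyperparameters
# from mcfg: d_state, dt_rank, expand (E = round(expand * C)), conv_branch.
add_vm_block <- function(P, prefix, C, mcfg) {
  E <- round(mcfg$expand * C)
  d <- mcfg$d_state
  r <- mcfg$dt_rank
  P <- add_norm(P, paste0(prefix, ".ln"), C)
  P <- add_conv(P, paste0(prefix, ".in"), 1L, C, E)
  if (isTRUE(mcfg$conv_branch))
    P <- add_conv(P, paste0(prefix, ".dw"), 3L, E, E, groups = E)
  for (k in 1:4) {
    P <- add_linear(P, paste0(prefix, ".xproj", k), E, r + 2L * d, bias = FALSE)
    P <- add_linear(P, paste0(prefix, ".dt", k), r, E, bias = FALSE)
    # softplus(dt_bias) spread over [1e-3, 0.1], the usual S6 step-size prior
    dt0 <- exp(stats::runif(E, log(1e-3), log(0.1)))
    P[[paste0(prefix, ".dt", k, ".b")]] <-
      ad_tensor(log(expm1(dt0)), requires_grad = TRUE)
    P[[paste0(prefix, ".A_log", k)]] <-
      ad_tensor(matrix(log(seq_len(d)), E, d, byrow = TRUE), requires_grad = TRUE)
    P[[paste0(prefix, ".D", k)]] <- ad_tensor(rep(1, E), requires_grad = TRUE)
  }
  P <- add_norm(P, paste0(prefix, ".outln"), E)
  add_conv(P, paste0(prefix, ".out"), 1L, E, C)
}

# SS2D core: LN -> in-projection -> (optional depthwise conv) -> SiLU ->
# four-direction selective scan -> merge -> LN -> out-projection.
vm_core <- function(P, prefix, x, mcfg) {
  d <- dim(ad_val(x))
  H <- d[1]; W <- d[2]
  E <- length(ad_val(P[[paste0(prefix, ".in.b")]]))
  dst <- mcfg$d_state
  r <- mcfg$dt_rank
  xn <- ln_fw(P, paste0(prefix, ".ln"), x)
  u <- conv_fw(P, paste0(prefix, ".in"), xn, 1L)
  if (isTRUE(mcfg$conv_branch))
    u <- conv_fw(P, paste0(prefix, ".dw"), u, 3L, groups = E)
  u <- ad_silu(u)
  perms <- scan_perms(H, W)
  ys <- vector("list", 4L)
  for (k in 1:4) {
    seq_k <- ad_gather_tokens(u, perms[[k]])
    proj <- ad_matmul(P[[paste0(prefix, ".xproj", k, ".w")]], seq_k)
    dtr <- ad_rows(proj, seq_len(r))
    B <- ad_rows(proj, r + seq_len(dst))
    Cm <- ad_rows(proj, r + dst + seq_len(dst))
    delta <- ad_softplus(ad_add_colvec(
      ad_matmul(P[[paste0(prefix, ".dt", k, ".w")]], dtr),
      P[[paste0(prefix, ".dt", k, ".b")]]))
    A <- ad_neg_exp(P[[paste0(prefix, ".A_log", k)]])
    ys[[k]] <- ad_selective_scan(seq_k, delta, A, B, Cm,
                                 P[[paste0(prefix, ".D", k)]])
  }
  merged <- ad_scatter_merge(ys, perms, H, W)
  merged <- ln_fw(P, paste0(prefix, ".outln"), merged)
  conv_fw(P, paste0(prefix, ".out"), merged, 1L)
}

# v1 * SS2D_core(LN(x)) + v2 * x ; shape-preserving
vm_block_fw <- function(P, prefix, x, mcfg, v1 = 1, v2 = 1) {
  if (v1 == 0) return(if (v2 == 1) x else ad_scale(x, v2))
  core <- vm_core(P, prefix, x, mcfg)
  if (v2 == 0) return(if (v1 == 1) core else ad_scale(core, v1))
  ad_add(if (v1 == 1) core else ad_scale(core, v1),
         if (v2 == 1) x else ad_scale(x, v2))
}

#' Create a standalone vision-Mamba block
#'
#' Builds one shape-preserving block for direct use and testing; inside the
#' network the same construction is used per encoder/decoder stage.
#'
#' @param channels number of input/output channels
#' @param d_state per-channel hidden state size of the S6 recurrence
#' @param expand width multiplier of the inner projection
#' @param dt_rank rank of the step-size projection
#' @param conv_branch add a depthwise 3x3 convolution before the scan?
#' @param seed RNG seed for weight initialization
#' @return object of class `vm_block`
#' @export
new_vm_block <- function(channels, d_state = 8, expand = 1, dt_rank = 1,
                         conv_branch = FALSE, seed = 1) {
  set.seed(seed)
  mcfg <- list(d_state = as.integer(d_state), expand = expand,
               dt_rank = as.integer(dt_rank), conv_branch = conv_branch)
  P <- list()
  P <- add_vm_block(P, "vm", as.integer(channels), mcfg)
  structure(list(params = P, mcfg = mcfg, channels = as.integer(channels)),
            class = "vm_block")
}

#' Apply a vision-Mamba block to a feature map
#'
#' Computes `v1 * SS2D(LN(x)) + v2 * x`; `v1 = 0, v2 = 1` is the identity.
#'
#' @param block a `vm_block`
#' @param x numeric array (H, W, C)
#' @param v1,v2 weights of the scan path and the residual path
#' @return numeric array (H, W, C), same shape as `x`
#' @export
vision_mamba_block <- function(block, x, v1 = 1, v2 = 1) {
  stopifnot(inherits(block, "vm_block"))
  if (dim(x)[3] != block$channels)
    stop("vision_mamba_block: channel mismatch between block and input")
  ad_no_grad(ad_val(vm_block_fw(block$params, "vm", ad_tensor(x), block$mcfg,
                                v1 = v1, v2 = v2)))
}
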