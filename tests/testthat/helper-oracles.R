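# Shared test utilities: numerical gradients and straight-line loop oracles
# kept deliberately independent of the package's kernels.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# plain R convolution oracle, channels-last, weight (k, k, cin/g, cout)
conv_ref <- function(x, w, b, k, stride = 1, pad = (k - 1) %/% 2, groups = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  cout <- dim(w)[4]
  cing <- C / groups; coutg <- cout / groups
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, cout))
  for (g in 0:(groups - 1)) for (co in 1:coutg) {
    oc <- g * coutg + co
    for (ho in 1:Ho) for (wo in 1:Wo) {
      s <- b[oc]
      for (ci in 1:cing) for (kh in 1:k) for (kw in 1:k) {
        hi <- (ho - 1) * stride - pad + kh
        wi <- (wo - 1) * stride - pad + kw
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          s <- s + x[hi, wi, g * cing + ci] * w[kh, kw, ci, oc]
      }
      out[ho, wo, oc] <- s
    }
  }
  out
}

# unrolled per-token selective-scan oracle (exact ZOH discretization)
selscan_ref <- function(x, delta, A, B, Cm, D) {
  E <- nrow(x); L <- ncol(x); d <- ncol(A)
  h <- matrix(0, E, d)
  y <- matrix(0, E, L)
  for (t in 1:L) {
    for (e in 1:E) for (j in 1:d) {
      edA <- exp(delta[e, t] * A[e, j])
      h[e, j] <- edA * h[e, j] + ((edA - 1) / A[e, j]) * B[j, t] * x[e, t]
    }
    y[, t] <- h %*% Cm[, t] + D * x[, t]
  }
  y
}

# pure-R layer norm over the channel axis at each position
ln_ref <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  mu <- rowMeans(xm)
  va <- rowMeans(xm^2) - mu^2
  xh <- (xm - mu) / sqrt(va + eps)
  array(sweep(xh, 2, g, `*`) + rep(b, each = d[1] * d[2]), dim = d)
}

rand_cube <- function(H, W, C) array(stats::rnorm(H * W * C), c(H, W, C))

# small model config for fast end-to-end tests
tiny_config <- function(size = 32, seed = 7) default_config(input_size = size, seed = seed)

make_pairs <- function(n, size = 32, seed0 = 100) {
  imgs <- list(); msks <- list()
  for (i in seq_len(n)) {
    p <- lesion_params(seed = seed0 + i, image_size = size, blur_sigma = 1,
                       hair_count = 1)
    pr <- generate_pair(p)
    imgs[[i]] <- pr$image; msks[[i]] <- pr$mask
  }
  list(images = imgs, masks = msks)
}
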