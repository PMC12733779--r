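# Reverse-mode automatic differentiation on a dynamic tape.
#
# Values are plain numeric arrays: feature maps are (H, W, C) cubes
# (channels-last), token batches are (E x L) matrices with one column per
# token. Each operation records a backward closure; ad_backward() walks the
# tape in reverse creation order and accumulates gradients into leaves.

.ad <- new.env(parent = emptyenv())
.ad$enabled <- TRUE
.ad$id <- 0L

#' Evaluate an expression without recording gradients
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
ad_no_grad <- function(expr) {
  old <- .ad$enabled
  .ad$enabled <- FALSE
  on.exit(.ad$enabled <- old)
  force(expr)
}

#' Create a tensor node
#' @param value numeric array, matrix or vector
#' @param requires_grad should gradients be accumulated into this node?
#' @return an `ad_tensor`
#' @export
ad_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  .ad$id <- .ad$id + 1L
  t$id <- .ad$id
  t$v <- value
  t$grad <- NULL
  t$req <- isTRUE(requires_grad) && .ad$enabled
  t$leaf <- TRUE
  t$parents <- NULL
  t$bw <- NULL
  class(t) <- "ad_tensor"
  t
}

is_tensor <- function(x) inherits(x, "ad_tensor")

#' Extract the value of a tensor (or pass through a plain array)
#' @param x tensor or array
#' @return numeric array
#' @export
ad_val <- function(x) if (is_tensor(x)) x$v else x

as_tensor <- function(x) if (is_tensor(x)) x else ad_tensor(x)

# Register an op. bw(g) must return a list of gradients, one per parent
# (NULL allowed for parents that do not require grad).
ad_op <- function(value, parents, bw) {
  parents <- lapply(parents, as_tensor)
  need <- .ad$enabled && any(vapply(parents, function(p) p$req, logical(1)))
  out <- ad_tensor(value)
  if (need) {
    out$req <- TRUE
    out$leaf <- FALSE
    out$parents <- parents
    out$bw <- bw
  }
  out
}

#' Run backpropagation from a scalar tensor
#' @param t scalar `ad_tensor`
#' @export
ad_backward <- function(t) {
  stopifnot(is_tensor(t), length(t$v) == 1L)
  # collect reachable subgraph
  nodes <- new.env(parent = emptyenv())
  stack <- list(t)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- n
    if (!is.null(n$parents)) stack <- c(stack, n$parents)
  }
  ids <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  t$grad <- if (is.null(dim(t$v))) 1 else array(1, dim = dim(t$v))
  for (id in ids) {
    n <- nodes[[as.character(id)]]
    if (is.null(n$bw) || is.null(n$grad)) next
    gs <- n$bw(n$grad)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      if (!p$req || is.null(gs[[i]])) next
      if (is.null(p$grad)) p$grad <- gs[[i]] else p$grad <- p$grad + gs[[i]]
    }
    if (!n$leaf) n$grad <- NULL  # free intermediate grads
  }
  invisible(t)
}

#' Reset gradients on a list of parameter tensors
#' @param params list of `ad_tensor`
#' @export
ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

keep_dim <- function(g, template) {
  if (!is.null(dim(template))) dim(g) <- dim(template)
  g
}

# ---- elementwise --------------------------------------------------------

ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_op(av + bv, list(a, b), function(g) {
    gb <- if (length(bv) == 1L) sum(g) else g
    ga <- if (length(av) == 1L) sum(g) else g
    list(ga, gb)
  })
}

ad_sub <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_op(av - bv, list(a, b), function(g) list(g, if (length(bv) == 1L) -sum(g) else -g))
}

ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_op(av * bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g * bv) else keep_dim(g * bv, av)
    gb <- if (length(bv) == 1L) sum(g * av) else keep_dim(g * av, bv)
    list(ga, gb)
  })
}

ad_scale <- function(a, s) {
  av <- ad_val(a)
  ad_op(av * s, list(a), function(g) list(g * s))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ad_val(a)))
  ad_op(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_relu <- function(a) {
  av <- ad_val(a)
  m <- av > 0
  ad_op(av * m, list(a), function(g) list(g * m))
}

ad_silu <- function(a) {
  av <- ad_val(a)
  s <- 1 / (1 + exp(-av))
  ad_op(av * s, list(a), function(g) list(g * (s + av * s * (1 - s))))
}

ad_softplus <- function(a) {
  av <- ad_val(a)
  out <- keep_dim(pmax(av, 0) + log1p(exp(-abs(av))), av)
  ad_op(out, list(a), function(g) list(g / (1 + exp(-av))))
}

# sum an (H, W, C) gradient over channels into an (H, W, 1) map
sum_channels <- function(g, d) {
  array(.rowSums(g, d[1] * d[2], d[3]), dim = c(d[1], d[2], 1))
}

# broadcast a single-channel map (H, W, 1) additively over all channels
ad_add_bcast <- function(x, m) {
  xv <- ad_val(x); mv <- ad_val(m)
  out <- xv + as.vector(mv)
  ad_op(out, list(x, m), function(g) list(g, sum_channels(g, dim(xv))))
}

# multiply by a single-channel gate (H, W, 1), broadcast over channels
ad_mul_bcast <- function(x, m) {
  xv <- ad_val(x); mv <- ad_val(m)
  out <- xv * as.vector(mv)
  ad_op(out, list(x, m), function(g)
    list(keep_dim(g * as.vector(mv), xv), sum_channels(g * xv, dim(xv))))
}

# multiply by a per-channel gate given as an (1, 1, C) cube
ad_mul_chan <- function(x, v) {
  xv <- ad_val(x); vv <- ad_val(v)
  d <- dim(xv)
  gate <- rep(as.vector(vv), each = d[1] * d[2])
  ad_op(keep_dim(xv * gate, xv), list(x, v), function(g) {
    gv <- vapply(seq_len(d[3]), function(c) sum(g[, , c] * xv[, , c]), numeric(1))
    list(keep_dim(g * gate, xv), array(gv, dim = dim(vv)))
  })
}

ad_concat_ch <- function(xs) {
  vals <- lapply(xs, ad_val)
  d <- dim(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, dim = c(d[1], d[2], sum(Cs)))
  at <- 0L
  for (v in vals) { out[, , at + seq_len(dim(v)[3])] <- v; at <- at + dim(v)[3] }
  ad_op(out, xs, function(g) {
    res <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      nc <- Cs[i]
      res[[i]] <- g[, , at + seq_len(nc), drop = FALSE]
      at <- at + nc
    }
    res
  })
}

ad_sum <- function(a) {
  av <- ad_val(a)
  ad_op(sum(av), list(a), function(g)
    list(keep_dim(array(g, dim = c(length(av))), av)))
}

# scalar / scalar division
ad_div <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_op(av / bv, list(a, b), function(g) list(g / bv, -g * av / bv^2))
}

ad_mean <- function(a) {
  av <- ad_val(a)
  n <- length(av)
  ad_op(mean(av), list(a), function(g) list(keep_dim(array(g / n, dim = c(length(av))), av)))
}

# ---- linear algebra -----------------------------------------------------

ad_matmul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_op(av %*% bv, list(a, b), function(g) list(g %*% t(bv), t(av) %*% g))
}

# add a column vector to every column of a matrix
ad_add_colvec <- function(m, v) {
  mv <- ad_val(m); vv <- ad_val(v)
  ad_op(mv + as.vector(vv), list(m, v), function(g) list(g, keep_dim(rowSums(g), vv)))
}

ad_softmax_rows <- function(a) {
  av <- ad_val(a)
  mx <- apply(av, 1, max)
  e <- exp(av - mx)
  s <- e / rowSums(e)
  ad_op(s, list(a), function(g) {
    dot <- rowSums(g * s)
    list((g - dot) * s)
  })
}

ad_rows <- function(m, idx) {
  mv <- ad_val(m)
  ad_op(mv[idx, , drop = FALSE], list(m), function(g) {
    gm <- matrix(0, nrow(mv), ncol(mv))
    gm[idx, ] <- g
    list(gm)
  })
}

# A = -exp(A_log): keeps the state matrix strictly negative
ad_neg_exp <- function(a) {
  av <- ad_val(a)
  out <- -exp(av)
  ad_op(out, list(a), function(g) list(g * out))
}

# ---- shape --------------------------------------------------------------

ad_reshape <- function(a, dims) {
  av <- ad_val(a)
  out <- av
  dim(out) <- dims
  old <- dim(av)
  ad_op(out, list(a), function(g) { dim(g) <- old; list(g) })
}

# (H, W, C) cube -> (C x L) token matrix, tokens in column-major (col_fwd) order
ad_tokens <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  L <- d[1] * d[2]
  out <- t(matrix(xv, L, d[3]))
  ad_op(out, list(x), function(g) list(array(t(g), dim = d)))
}

ad_untokens <- function(m, H, W) {
  mv <- ad_val(m)
  C <- nrow(mv)
  out <- array(t(mv), dim = c(H, W, C))
  ad_op(out, list(m), function(g) list(t(matrix(g, H * W, C))))
}

# gather tokens along a scan direction: perm maps sequence index -> grid index
ad_gather_tokens <- function(x, perm) {
  xv <- ad_val(x)
  d <- dim(xv)
  L <- d[1] * d[2]
  base <- matrix(xv, L, d[3])
  out <- t(base[perm, , drop = FALSE])
  ad_op(out, list(x), function(g) {
    gm <- matrix(0, L, d[3])
    gm[perm, ] <- t(g)
    list(array(gm, dim = d))
  })
}

# merge four directional sequences back onto the grid and sum
ad_scatter_merge <- function(ys, perms, H, W) {
  E <- nrow(ad_val(ys[[1]]))
  L <- H * W
  acc <- matrix(0, L, E)
  for (k in seq_along(ys)) acc[perms[[k]], ] <- acc[perms[[k]], ] + t(ad_val(ys[[k]]))
  ad_op(array(acc, dim = c(H, W, E)), ys, function(g) {
    gm <- matrix(g, L, E)
    lapply(perms, function(p) t(gm[p, , drop = FALSE]))
  })
}

# ---- structured kernels -------------------------------------------------

ad_conv2d <- function(x, w, b, k, stride = 1L, pad = NULL, groups = 1L) {
  xv <- ad_val(x); wv <- ad_val(w); bv <- ad_val(b)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  cout <- length(bv)
  out <- cpp_conv2d_fw(xv, as.vector(wv), as.vector(bv), k, stride, pad, groups, cout)
  ad_op(out, list(x, w, b), function(g) {
    r <- cpp_conv2d_bw(xv, as.vector(wv), g, k, stride, pad, groups, cout)
    list(r$gx, keep_dim(as.vector(r$gw), wv), keep_dim(as.vector(r$gb), bv))
  })
}

ad_avgpool3 <- function(x) {
  xv <- ad_val(x)
  ad_op(cpp_avgpool3_fw(xv), list(x), function(g) list(cpp_avgpool3_bw(g)))
}

ad_upsample <- function(x, Ho, Wo) {
  xv <- ad_val(x)
  d <- dim(xv)
  ad_op(cpp_bilinear_fw(xv, Ho, Wo), list(x), function(g)
    list(cpp_bilinear_bw(g, d[1], d[2])))
}

ad_global_maxpool <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  idx <- vapply(seq_len(d[3]), function(c) which.max(xv[, , c]), integer(1))
  val <- vapply(seq_len(d[3]), function(c) xv[, , c][idx[c]], numeric(1))
  ad_op(array(val, dim = c(1, 1, d[3])), list(x), function(g) {
    gx <- array(0, dim = d)
    for (c in seq_len(d[3])) {
      sl <- gx[, , c]
      sl[idx[c]] <- g[1, 1, c]
      gx[, , c] <- sl
    }
    list(gx)
  })
}

# selective scan: seq (E x L), delta (E x L), A (E x d), B/Cm (d x L), D (E)
ad_selective_scan <- function(seq, delta, A, B, Cm, D) {
  sv <- ad_val(seq); dv <- ad_val(delta); Av <- ad_val(A)
  Bv <- ad_val(B); Cv <- ad_val(Cm); Dv <- ad_val(D)
  if (!all(is.finite(Av)) || !all(is.finite(Dv)))
    stop("selective scan: non-finite state-space parameters")
  need <- .ad$enabled && any(vapply(list(seq, delta, A, B, Cm, D),
                                    function(p) is_tensor(p) && p$req, logical(1)))
  fw <- cpp_selscan_fw(sv, dv, Av, Bv, Cv, as.vector(Dv), need)
  ad_op(fw$y, list(seq, delta, A, B, Cm, D), function(g) {
    r <- cpp_selscan_bw(sv, dv, Av, Bv, Cv, as.vector(Dv), fw$h, g)
    list(r$gx, r$gdelta, r$gA, r$gB, r$gC, keep_dim(as.vector(r$gD), Dv))
  })
}

# ---- normalization ------------------------------------------------------

# layer normalization across channels at every spatial position
ad_layernorm_ch <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ad_val(x); gv <- ad_val(gamma); bv <- ad_val(beta)
  d <- dim(xv)
  L <- d[1] * d[2]; C <- d[3]
  xm <- matrix(xv, L, C)
  mu <- rowMeans(xm)
  va <- rowMeans(xm * xm) - mu * mu
  inv <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * inv
  out <- array(sweep(xhat, 2, as.vector(gv), `*`) +
                 rep(as.vector(bv), each = L), dim = d)
  ad_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, L, C)
    ggamma <- colSums(gm * xhat)
    gbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, as.vector(gv), `*`)
    gx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(array(gx, dim = d), keep_dim(ggamma, gv), keep_dim(gbeta, bv))
  })
}

# layer normalization over the whole map (used on single-channel prompts)
ad_layernorm_all <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ad_val(x)
  n <- length(xv)
  mu <- mean(xv)
  va <- mean(xv^2) - mu^2
  inv <- 1 / sqrt(va + eps)
  xhat <- (xv - mu) * inv
  gv <- ad_val(gamma); bv <- ad_val(beta)
  ad_op(keep_dim(xhat * as.vector(gv) + as.vector(bv), xv),
        list(x, gamma, beta), function(g) {
    ggamma <- sum(g * xhat)
    gbeta <- sum(g)
    dxhat <- g * as.vector(gv)
    gx <- inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
    list(keep_dim(gx, xv), ggamma, gbeta)
  })
}

# batch normalization per channel over the spatial grid; running buffers are
# stored in `buf` (an environment) under `name`
ad_batchnorm <- function(x, gamma, beta, buf, name, training, momentum = 0.1,
                         eps = 1e-5) {
  xv <- ad_val(x)
  d <- dim(xv)
  L <- d[1] * d[2]; C <- d[3]
  xm <- matrix(xv, L, C)
  key_m <- paste0(name, ".running_mean"); key_v <- paste0(name, ".running_var")
  if (is.null(buf[[key_m]])) { buf[[key_m]] <- rep(0, C); buf[[key_v]] <- rep(1, C) }
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    buf[[key_m]] <- (1 - momentum) * buf[[key_m]] + momentum * mu
    n <- max(L, 2)
    buf[[key_v]] <- (1 - momentum) * buf[[key_v]] + momentum * va * n / (n - 1)
  } else {
    mu <- buf[[key_m]]
    va <- buf[[key_v]]
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xm, 2, mu) * rep(inv, each = L)
  gv <- ad_val(gamma); bv <- ad_val(beta)
  out <- array(sweep(xhat, 2, as.vector(gv), `*`) + rep(as.vector(bv), each = L),
               dim = d)
  ad_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, L, C)
    ggamma <- colSums(gm * xhat)
    gbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, as.vector(gv), `*`)
    if (training) {
      gx <- rep(inv, each = L) *
        (dxhat - rep(colMeans(dxhat), each = L) -
           xhat * rep(colMeans(dxhat * xhat), each = L))
    } else {
      gx <- dxhat * rep(inv, each = L)
    }
    list(array(gx, dim = d), keep_dim(ggamma, gv), keep_dim(gbeta, bv))
  })
}
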