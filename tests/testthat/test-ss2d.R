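# Cross-scan, selective scan and the vision-Mamba block.

test_that("cross_scan enumerates the four directions on a 2x2 grid", {
  x <- array(0, c(2, 2, 1))
  x[1, 1, 1] <- 1; x[1, 2, 1] <- 2; x[2, 1, 1] <- 3; x[2, 2, 1] <- 4
  s <- cross_scan(x)
  expect_equal(as.vector(s$row_fwd), c(1, 2, 3, 4))
  expect_equal(as.vector(s$row_bwd), c(4, 3, 2, 1))
  expect_equal(as.vector(s$col_fwd), c(1, 3, 2, 4))
  expect_equal(as.vector(s$col_bwd), c(4, 2, 3, 1))
})

test_that("cross_scan outputs are per-channel permutations of the input", {
  set.seed(11)
  x <- rand_cube(3, 3, 1)
  s <- cross_scan(x)
  for (k in 1:4) expect_equal(sort(as.vector(s[[k]])), sort(as.vector(x)))
  expect_equal(cross_scan(array(0, c(2, 3, 2)))$row_fwd, matrix(0, 2, 6))
  expect_error(cross_scan(array(1, c(0, 2, 1))), "empty|dims")
})

test_that("scan expand/merge is an exact bijection for all grids up to 8x8", {
  set.seed(12)
  for (H in 1:8) for (W in 1:8) {
    x <- rand_cube(H, W, 2)
    s <- cross_scan(x)
    # merging the four raw scans yields 4x the input
    expect_equal(scan_merge(s, H, W), 4 * x, tolerance = 1e-12)
    # each direction individually reconstructs the input exactly
    perms <- mambaseg:::scan_perms(H, W)
    for (k in 1:4) {
      back <- matrix(0, H * W, 2)
      back[perms[[k]], ] <- t(s[[k]])
      expect_identical(array(back, dim = c(H, W, 2)), x)
    }
  }
})

test_that("scan_merge matches an index-by-index replacement oracle", {
  set.seed(13)
  H <- 4; W <- 5; C <- 3
  ys <- lapply(1:4, function(k) matrix(rnorm(C * H * W), C, H * W))
  got <- scan_merge(ys, H, W)
  perms <- mambaseg:::scan_perms(H, W)
  want <- array(0, c(H, W, C))
  for (k in 1:4) for (t in seq_len(H * W)) {
    gi <- perms[[k]][t]
    h <- (gi - 1) %% H + 1
    w <- (gi - 1) %/% H + 1
    want[h, w, ] <- want[h, w, ] + ys[[k]][, t]
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(scan_merge(lapply(1:4, function(k) matrix(0, C, 7)), H, W),
               "length")
})

test_that("merging the raw scans of the 2x2 example quadruples it", {
  x <- array(c(1, 3, 2, 4), c(2, 2, 1))
  expect_equal(scan_merge(cross_scan(x), 2, 2), 4 * x)
})

test_that("selective scan handles zero input and the small-step limit", {
  E <- 3; L <- 6; d <- 2
  set.seed(14)
  A <- -matrix(runif(E * d, 0.5, 2), E)
  B <- matrix(rnorm(d * L), d); Cm <- matrix(rnorm(d * L), d)
  D <- rnorm(E)
  delta <- matrix(runif(E * L, 0.05, 0.5), E)
  expect_equal(selective_scan(matrix(0, E, L), delta, A, B, Cm, D),
               matrix(0, E, L))
  # delta -> 0: decay -> identity, input gain -> 0, y -> D * x
  x <- matrix(rnorm(E * L), E)
  y <- selective_scan(x, matrix(1e-9, E, L), A, B, Cm, D)
  expect_equal(y, x * D, tolerance = 1e-6)
})

test_that("scalar-state scan reproduces the closed-form geometric decay", {
  # A = -1, delta = 1, B = C = 1, D = 0, x = (1,0,0,0):
  # y_t = (1 - e^-1) * e^-(t-1)
  y <- selective_scan(matrix(c(1, 0, 0, 0), 1), matrix(1, 1, 4),
                      matrix(-1, 1, 1), matrix(1, 1, 4), matrix(1, 1, 4), 0)
  expect_equal(as.vector(y), (1 - exp(-1)) * exp(-(0:3)), tolerance = 1e-10)
})

test_that("selective scan agrees with the unrolled loop oracle", {
  set.seed(15)
  for (case in list(c(E = 2, L = 16, d = 1), c(E = 4, L = 64, d = 3))) {
    E <- case["E"]; L <- case["L"]; d <- case["d"]
    x <- matrix(rnorm(E * L), E)
    delta <- matrix(runif(E * L, 0.01, 1), E)
    A <- -matrix(runif(E * d, 0.2, 3), E)
    B <- matrix(rnorm(d * L), d); Cm <- matrix(rnorm(d * L), d)
    D <- rnorm(E)
    expect_equal(selective_scan(x, delta, A, B, Cm, D),
                 selscan_ref(x, delta, A, B, Cm, D), tolerance = 1e-5)
  }
  expect_error(selective_scan(matrix(1, 1, 2), matrix(1, 1, 2),
                              matrix(NaN, 1, 1), matrix(1, 1, 2),
                              matrix(1, 1, 2), 0), "finite")
})

test_that("hidden state stays bounded over 10^4 tokens with negative A", {
  set.seed(16)
  L <- 10000
  x <- matrix(sin(seq_len(L) / 7), 1)
  delta <- matrix(runif(L, 0.05, 0.5), 1)
  y <- selective_scan(x, delta, matrix(-0.5, 1, 1),
                      matrix(rnorm(L), 1), matrix(rnorm(L), 1), 1)
  expect_true(all(is.finite(y)))
  expect_lt(max(abs(y)), 100)
})

test_that("vision-Mamba block is shape-preserving and has an identity limit", {
  set.seed(17)
  for (C in c(8, 16, 24, 32, 40)) {
    blk <- new_vm_block(C, d_state = 4, expand = 1.5, dt_rank = 2, seed = C)
    x <- rand_cube(6, 5, C)
    expect_equal(dim(vision_mamba_block(blk, x)), dim(x))
  }
  blk <- new_vm_block(8, seed = 1)
  x <- rand_cube(4, 4, 8)
  expect_identical(vision_mamba_block(blk, x, v1 = 0, v2 = 1), x)
  expect_error(vision_mamba_block(blk, rand_cube(4, 4, 5)), "channel")
})

test_that("vision-Mamba block matches a hand-rolled sequential oracle", {
  set.seed(18)
  C <- 4
  blk <- new_vm_block(C, d_state = 3, expand = 1, dt_rank = 2, seed = 5)
  x <- rand_cube(4, 4, C)
  got <- vision_mamba_block(blk, x, v1 = 1, v2 = 1)

  # straight-line re-computation from the block's own weights
  P <- lapply(blk$params, ad_val)
  E <- C; d <- 3; r <- 2; H <- 4; W <- 4
  xn <- ln_ref(x, P[["vm.ln.g"]], P[["vm.ln.b"]])
  u <- conv_ref(xn, P[["vm.in.w"]], P[["vm.in.b"]], 1)
  u <- u / (1 + exp(-u))                       # SiLU
  perms <- mambaseg:::scan_perms(H, W)
  base <- matrix(u, H * W, E)
  acc <- matrix(0, H * W, E)
  for (k in 1:4) {
    seq_k <- t(base[perms[[k]], ])
    proj <- P[[paste0("vm.xproj", k, ".w")]] %*% seq_k
    dtr <- proj[1:r, , drop = FALSE]
    B <- proj[r + (1:d), , drop = FALSE]
    Cmat <- proj[r + d + (1:d), , drop = FALSE]
    zr <- P[[paste0("vm.dt", k, ".w")]] %*% dtr + P[[paste0("vm.dt", k, ".b")]]
    delta <- log1p(exp(-abs(zr))) + pmax(zr, 0)  # softplus
    A <- -exp(P[[paste0("vm.A_log", k)]])
    yk <- selscan_ref(seq_k, delta, A, B, Cmat, P[[paste0("vm.D", k)]])
    acc[perms[[k]], ] <- acc[perms[[k]], ] + t(yk)
  }
  merged <- ln_ref(array(acc, c(H, W, E)), P[["vm.outln.g"]], P[["vm.outln.b"]])
  want <- conv_ref(merged, P[["vm.out.w"]], P[["vm.out.b"]], 1) + x
  expect_equal(got, want, tolerance = 1e-8)
})
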