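# Context-enhanced decoder: multi-scale branches and the EASC gate chain.

make_dec <- function(C = 8, t = 1, cfg = tiny_config(), seed = 41) {
  set.seed(seed)
  P <- mambaseg:::add_mca_stage(list(), t, C, cfg)
  list(P = P, cfg = cfg)
}

test_that("multi-scale branches split channels 4 ways and restore them", {
  st <- make_dec(C = 8)
  x <- rand_cube(6, 6, 8)
  out <- mambaseg:::multiscale_fw(st$P, "dec1", ad_tensor(x), st$cfg)
  expect_equal(dim(ad_val(out)), c(6, 6, 8))
  expect_equal(st$cfg$branch_kernels, c(3, 5, 7, 9))
  for (i in 1:4)
    expect_equal(dim(ad_val(st$P[[sprintf("dec1.br%d.dw.w", i)]]))[1],
                 2 * i + 1)
  expect_error(mambaseg:::add_mca_stage(list(), 1, 6L, st$cfg), "divisible")
})

test_that("delta depthwise kernels with selector pointwise maps pass through", {
  st <- make_dec(C = 8)
  C <- 8
  for (i in 1:4) {
    k <- st$cfg$branch_kernels[i]
    wd <- array(0, c(k, k, 1, C))
    wd[(k + 1) / 2, (k + 1) / 2, 1, ] <- 1          # delta kernel
    st$P[[sprintf("dec1.br%d.dw.w", i)]]$v <- wd
    st$P[[sprintf("dec1.br%d.dw.b", i)]]$v <- rep(0, C)
    wp <- array(0, c(1, 1, C, C / 4))               # select channels of branch i
    for (o in 1:(C / 4)) wp[1, 1, (i - 1) * (C / 4) + o, o] <- 1
    st$P[[sprintf("dec1.br%d.pw.w", i)]]$v <- wp
    st$P[[sprintf("dec1.br%d.pw.b", i)]]$v <- rep(0, C / 4)
  }
  x <- rand_cube(5, 7, 8)
  out <- mambaseg:::multiscale_fw(st$P, "dec1", ad_tensor(x), st$cfg)
  expect_equal(ad_val(out), x, tolerance = 1e-12)
})

test_that("context embedding is shape-preserving and matches its oracle", {
  st <- make_dec(C = 8, seed = 42)
  x <- rand_cube(5, 5, 8)
  out <- mambaseg:::context_embed_fw(st$P, "dec1", ad_tensor(x), new.env(), FALSE)
  expect_equal(dim(ad_val(out)), c(5, 5, 8))
  P <- lapply(st$P, ad_val)
  h <- conv_ref(x, P[["dec1.ce.dw.w"]], P[["dec1.ce.dw.b"]], 3, 1, 1, 8)
  h <- conv_ref(h, P[["dec1.ce.pw.w"]], P[["dec1.ce.pw.b"]], 1)
  # eval-mode BN with fresh buffers: mean 0, var 1
  want <- h
  for (c in 1:8) want[, , c] <- h[, , c] / sqrt(1 + 1e-5) * P[["dec1.ce.bn.g"]][c] +
      P[["dec1.ce.bn.b"]][c]
  expect_equal(ad_val(out), want, tolerance = 1e-8)
})

test_that("edge gate preserves zero and brackets positive inputs", {
  st <- make_dec(C = 4, seed = 43)
  z <- array(0, c(6, 6, 4))
  expect_equal(ad_val(mambaseg:::ee_fw(st$P, "dec1", ad_tensor(z), new.env(), TRUE)),
               z)
  x <- array(runif(6 * 6 * 4, 0.1, 2), c(6, 6, 4))
  fee <- ad_val(mambaseg:::ee_fw(st$P, "dec1", ad_tensor(x), new.env(), TRUE))
  expect_true(all(fee > x) && all(fee < 2 * x))
})

test_that("edge gate matches a straight-line oracle", {
  st <- make_dec(C = 4, seed = 44)
  x <- rand_cube(6, 6, 4)
  got <- ad_val(mambaseg:::ee_fw(st$P, "dec1", ad_tensor(x), new.env(), FALSE))
  P <- lapply(st$P, ad_val)
  sm <- conv_ref(x, P[["dec1.ee.dw.w"]], P[["dec1.ee.dw.b"]], 7, 1, 3, 4)
  ap <- sm
  for (c in 1:4) {           # 3x3 zero-padded average pool, divisor 9
    padm <- matrix(0, 8, 8)
    padm[2:7, 2:7] <- sm[, , c]
    for (i in 1:6) for (j in 1:6) ap[i, j, c] <- sum(padm[i:(i + 2), j:(j + 2)]) / 9
  }
  xbar <- x - ap
  for (c in 1:4) xbar[, , c] <- xbar[, , c] / sqrt(1 + 1e-5) *
      P[["dec1.ee.bn.g"]][c] + P[["dec1.ee.bn.b"]][c]
  gate <- 1 / (1 + exp(-conv_ref(xbar, P[["dec1.ee.pw.w"]], P[["dec1.ee.pw.b"]], 1)))
  want <- x * as.vector(gate[, , 1]) + x
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("spatial gate uses the 7-3-1 schedule and brackets positive inputs", {
  st <- make_dec(C = 4, seed = 45)
  expect_equal(dim(ad_val(st$P[["dec1.sa.dw1.w"]]))[1], 7)
  expect_equal(dim(ad_val(st$P[["dec1.sa.dw2.w"]]))[1], 3)
  expect_equal(dim(ad_val(st$P[["dec1.sa.pw.w"]]))[3:4], c(4, 1))
  x <- array(runif(6 * 6 * 4, 0.1, 2), c(6, 6, 4))
  fsa <- ad_val(mambaseg:::sa_fw(st$P, "dec1", ad_tensor(x), st$cfg, new.env(), TRUE))
  expect_true(all(fsa > x) && all(fsa < 2 * x))
  # straight-line oracle (eval mode)
  got <- ad_val(mambaseg:::sa_fw(st$P, "dec1", ad_tensor(x), st$cfg, new.env(), FALSE))
  P <- lapply(st$P, ad_val)
  bn_id <- function(h, g, b) {
    for (c in seq_along(g)) h[, , c] <- h[, , c] / sqrt(1 + 1e-5) * g[c] + b[c]
    h
  }
  s1 <- bn_id(conv_ref(x, P[["dec1.sa.dw1.w"]], P[["dec1.sa.dw1.b"]], 7, 1, 3, 4),
              P[["dec1.sa.bn1.g"]], P[["dec1.sa.bn1.b"]])
  s2 <- bn_id(conv_ref(s1, P[["dec1.sa.dw2.w"]], P[["dec1.sa.dw2.b"]], 3, 1, 1, 4),
              P[["dec1.sa.bn2.g"]], P[["dec1.sa.bn2.b"]])
  gate <- 1 / (1 + exp(-pmax(conv_ref(s2, P[["dec1.sa.pw.w"]],
                                      P[["dec1.sa.pw.b"]], 1), 0)))
  want <- x * as.vector(gate[, , 1]) + x
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("channel gate pools constants exactly and matches its oracle", {
  st <- make_dec(C = 8, seed = 46)
  v <- rnorm(8)
  xc <- array(rep(v, each = 16), c(4, 4, 8))
  pooled <- ad_val(ad_global_maxpool(ad_tensor(xc)))
  expect_equal(as.vector(pooled), v)
  z <- array(0, c(4, 4, 8))
  expect_equal(ad_val(mambaseg:::ca_fw(st$P, "dec1", ad_tensor(z))), z)
  x <- rand_cube(4, 4, 8)
  got <- ad_val(mambaseg:::ca_fw(st$P, "dec1", ad_tensor(x)))
  P <- lapply(st$P, ad_val)
  mx <- apply(x, 3, max)
  w1 <- matrix(P[["dec1.ca.fc1.w"]], 8, 8)   # (1,1,C,C) -> C x C
  w2 <- matrix(P[["dec1.ca.fc2.w"]], 8, 8)
  w <- pmax(as.vector(mx %*% w1) + P[["dec1.ca.fc1.b"]], 0)
  gate <- 1 / (1 + exp(-(as.vector(w %*% w2) + P[["dec1.ca.fc2.b"]])))
  want <- x
  for (c in 1:8) want[, , c] <- x[, , c] * gate[c] + x[, , c]
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("full decoder stage preserves shape and composes its parts", {
  cfg <- tiny_config()
  st <- make_dec(C = 8, cfg = cfg, seed = 47)
  x <- rand_cube(8, 8, 8)
  buf <- new.env()
  got <- ad_val(mambaseg:::mca_stage_fw(st$P, 1L, ad_tensor(x), cfg, buf, FALSE))
  expect_equal(dim(got), c(8, 8, 8))
  # composition of the exported pieces equals the stage forward
  buf2 <- new.env()
  f_vmt <- mambaseg:::vm_block_fw(st$P, "dec1.vm", ad_tensor(x),
                                  mambaseg:::stage_mcfg(cfg$dec_mamba, 1L))
  f <- mambaseg:::multiscale_fw(st$P, "dec1", f_vmt, cfg)
  f <- mambaseg:::context_embed_fw(st$P, "dec1", f, buf2, FALSE)
  f <- mambaseg:::ee_fw(st$P, "dec1", f, buf2, FALSE)
  f <- mambaseg:::sa_fw(st$P, "dec1", f, cfg, buf2, FALSE)
  f <- mambaseg:::ca_fw(st$P, "dec1", f)
  expect_equal(got, ad_val(f) + ad_val(f_vmt), tolerance = 1e-10)
})

test_that("gate ablation switches drop the corresponding parameters", {
  cfg <- tiny_config()
  cfg$use_ee <- FALSE; cfg$use_sa <- FALSE; cfg$use_ca <- FALSE
  st <- make_dec(C = 8, cfg = cfg, seed = 48)
  expect_false(any(grepl("\\.ee\\.|\\.sa\\.|\\.ca\\.", names(st$P))))
  out <- mambaseg:::mca_stage_fw(st$P, 1L, ad_tensor(rand_cube(8, 8, 8)), cfg,
                                 new.env(), FALSE)
  expect_equal(dim(ad_val(out)), c(8, 8, 8))
})
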