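# Context prompt encoder stage: inverted-pyramid conv, global/local fusion,
# self-prompt masks.

make_stage <- function(cin = 3, cout = 8, t = 1, cfg = tiny_config(), seed = 31) {
  set.seed(seed)
  P <- mambaseg:::add_pcm_stage(list(), t, cin, cout, cfg)
  list(P = P, cfg = cfg)
}

test_that("inverted-pyramid conv follows the stride/channel contract", {
  st <- make_stage(cin = 3, cout = 16)
  cfg <- st$cfg
  cfg$stage_strides <- c(2L, 2L, 2L, 2L, 2L)
  x <- ad_tensor(rand_cube(64, 64, 3))
  out <- mambaseg:::ipc_fw(st$P, "enc1", x, cfg, 2L)
  expect_equal(dim(ad_val(out)), c(32, 32, 16))
  out1 <- mambaseg:::ipc_fw(st$P, "enc1", x, cfg, 1L)
  expect_equal(dim(ad_val(out1)), c(64, 64, 16))
})

test_that("zero input with zero biases maps to zero through the conv path", {
  st <- make_stage(cin = 3, cout = 8)
  for (nm in grep("^enc1\\.ipc\\..*\\.b$", names(st$P), value = TRUE))
    st$P[[nm]]$v <- 0 * st$P[[nm]]$v
  out <- mambaseg:::ipc_fw(st$P, "enc1", ad_tensor(array(0, c(16, 16, 3))),
                           st$cfg, 1L)
  expect_equal(ad_val(out), array(0, c(16, 16, 8)))
})

test_that("with lambda1 = 0 the fused features ignore the Mamba path", {
  cfg <- tiny_config()
  cfg$lambda1 <- 0
  cfg$use_prompts <- FALSE
  st1 <- make_stage(cfg = cfg, seed = 32)
  # a second stage with different Mamba weights but identical conv weights
  st2 <- make_stage(cfg = cfg, seed = 33)
  for (nm in grep("\\.vm\\.", names(st1$P), invert = TRUE, value = TRUE))
    st2$P[[nm]]$v <- st1$P[[nm]]$v
  x <- ad_tensor(rand_cube(16, 16, 3))
  buf <- new.env()
  o1 <- mambaseg:::pcm_stage_fw(st1$P, 1L, x, cfg, buf, FALSE)
  o2 <- mambaseg:::pcm_stage_fw(st2$P, 1L, x, cfg, buf, FALSE)
  expect_equal(ad_val(o1$f_et), ad_val(o2$f_et))
})

test_that("stage fusion reproduces a straight-line oracle of the equations", {
  cfg <- tiny_config()
  st <- make_stage(cin = 8, cout = 8, cfg = cfg, seed = 34)
  x <- rand_cube(8, 8, 8)
  buf <- new.env()
  o <- mambaseg:::pcm_stage_fw(st$P, 1L, ad_tensor(x), cfg, buf, FALSE)
  P <- lapply(st$P, ad_val)
  # f_ipc: large dw conv -> pw -> act -> small dw -> act -> pw
  relu <- function(v) pmax(v, 0)
  h <- conv_ref(x, P[["enc1.ipc.dwl.w"]], P[["enc1.ipc.dwl.b"]], 7, 1, 3, 8)
  h <- relu(conv_ref(h, P[["enc1.ipc.pw1.w"]], P[["enc1.ipc.pw1.b"]], 1))
  h <- relu(conv_ref(h, P[["enc1.ipc.dws.w"]], P[["enc1.ipc.dws.b"]], 3, 1, 1, 8))
  f_ipc <- conv_ref(h, P[["enc1.ipc.pw2.w"]], P[["enc1.ipc.pw2.b"]], 1)
  expect_equal(ad_val(o$f_ipc), f_ipc, tolerance = 1e-10)
  # f_et = pw(lambda1 * f_m + lambda2 * f_ipc), with f_m from the block
  mix <- cfg$lambda1 * ad_val(o$f_m) + cfg$lambda2 * f_ipc
  f_et <- conv_ref(mix, P[["enc1.fuse.w"]], P[["enc1.fuse.b"]], 1)
  expect_equal(ad_val(o$f_et), f_et, tolerance = 1e-10)
  # f_pt = f_et + p1 + p2 broadcast across channels (default prompt weights 1)
  f_pt <- f_et + as.vector(ad_val(o$p1)) + as.vector(ad_val(o$p2))
  expect_equal(ad_val(o$f_pt), f_pt, tolerance = 1e-10)
})

test_that("prompt masks are sigmoid maps strictly inside (0, 1)", {
  cfg <- tiny_config()
  st <- make_stage(cin = 3, cout = 8, cfg = cfg, seed = 35)
  x <- ad_tensor(10 * rand_cube(12, 12, 3))
  o <- mambaseg:::pcm_stage_fw(st$P, 1L, x, cfg, new.env(), TRUE)
  for (p in list(ad_val(o$p1), ad_val(o$p2))) {
    expect_equal(dim(p), c(12, 12, 1))
    expect_gt(min(p), 0)
    expect_lt(max(p), 1)
  }
})

test_that("zero prompt heads yield the constant 0.5 mask", {
  cfg <- tiny_config()
  st <- make_stage(cin = 3, cout = 8, cfg = cfg, seed = 36)
  for (nm in c("enc1.p1.w", "enc1.p1.b", "enc1.p2.w", "enc1.p2.b"))
    st$P[[nm]]$v <- 0 * st$P[[nm]]$v
  st$P[["enc1.p1bn.b"]]$v <- 0 * st$P[["enc1.p1bn.b"]]$v
  st$P[["enc1.p2ln.b"]]$v <- 0 * st$P[["enc1.p2ln.b"]]$v
  o <- mambaseg:::pcm_stage_fw(st$P, 1L, ad_tensor(rand_cube(8, 8, 3)), cfg,
                               new.env(), TRUE)
  expect_equal(ad_val(o$p1), array(0.5, c(8, 8, 1)))
  expect_equal(ad_val(o$p2), array(0.5, c(8, 8, 1)))
})

test_that("single-channel prompt head with unit weight is a pointwise sigmoid", {
  # eval-mode BN with fresh buffers (mean 0, var 1) is the identity affine
  cfg <- tiny_config()
  set.seed(37)
  P <- list()
  P <- mambaseg:::add_conv(P, "h", 1L, 1L, 1L)
  P <- mambaseg:::add_norm(P, "hbn", 1L)
  P[["h.w"]]$v <- array(1, c(1, 1, 1, 1))
  P[["h.b"]]$v <- 0
  x <- rand_cube(6, 6, 1)
  got <- ad_val(ad_sigmoid(mambaseg:::bn_fw(P, "hbn",
    mambaseg:::conv_fw(P, "h", ad_tensor(x), 1L), new.env(), FALSE)))
  expect_equal(got, 1 / (1 + exp(-x / sqrt(1 + 1e-5))), tolerance = 1e-8)
})

test_that("prompt weights 0 reduce the stage output to the fused features", {
  cfg <- tiny_config()
  cfg$prompt_lambda1 <- 0
  cfg$prompt_lambda2 <- 0
  st <- make_stage(cin = 3, cout = 8, cfg = cfg, seed = 38)
  o <- mambaseg:::pcm_stage_fw(st$P, 1L, ad_tensor(rand_cube(8, 8, 3)), cfg,
                               new.env(), FALSE)
  expect_equal(ad_val(o$f_pt), ad_val(o$f_et))
})

test_that("constant feature plus constant 0.5 prompts gives 1.0 everywhere", {
  cfg <- tiny_config()
  st <- make_stage(cin = 3, cout = 8, cfg = cfg, seed = 39)
  # zero the fusion conv and the prompt heads: f_et = 0, p1 = p2 = 0.5
  for (nm in c("enc1.fuse.w", "enc1.fuse.b", "enc1.p1.w", "enc1.p1.b",
               "enc1.p2.w", "enc1.p2.b", "enc1.p1bn.b", "enc1.p2ln.b"))
    st$P[[nm]]$v <- 0 * st$P[[nm]]$v
  o <- mambaseg:::pcm_stage_fw(st$P, 1L, ad_tensor(rand_cube(8, 8, 3)), cfg,
                               new.env(), TRUE)
  expect_equal(ad_val(o$f_pt), array(1, c(8, 8, 8)), tolerance = 1e-12)
})
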