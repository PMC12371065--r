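test_that("WAP is a scaled window mean, vanishing at gamma = 1", {
  expect_equal(wap(c(1, 2, 3, 4), gamma = 0), 2.5)
  expect_equal(wap(c(1, 2, 3, 4), gamma = 0.5), 1.25)
  set.seed(11)
  for (i in 1:10) expect_identical(wap(rnorm(sample(1:20, 1)), gamma = 1), 0)
})

test_that("WAP-BN matches a straight-line transcription and its limits", {
  z <- c(1, 2, 3, 4)
  expect_equal(wap_bn(z, gamma = 0, eps = 1e-5), ref_wap_bn(z, 0, 1e-5),
               tolerance = 1e-12)
  # forced S_J = 1 reduces to the substituted closed form
  d <- mean(z)
  s2 <- mean((z - d)^2)
  expect_equal(wap_bn(z, s_j = 1, eps = 1e-5),
               (z - d) / sqrt(s2 + 1 / (1 + exp(-1)) + 1e-5), tolerance = 1e-12)
  # constant window: numerator 0
  expect_equal(wap_bn(rep(3, 8)), rep(0, 8))
  # the printed gamma = 1 setting nulls WAP-BN identically (regression
  # test documenting the degeneracy behind the shipped default 0.5)
  set.seed(12)
  for (i in 1:5) expect_equal(wap_bn(rnorm(10), gamma = 1), rep(0, 10))
})

test_that("batch normalisation standardises and degenerates as expected", {
  set.seed(13)
  z <- rnorm(200, mean = 5, sd = 3)
  zh <- batch_norm(z)
  expect_equal(mean(zh), 0, tolerance = 1e-12)
  expect_equal(var(zh) * 199 / 200, 1, tolerance = 1e-4)  # eps-deflated
  expect_equal(batch_norm(rep(2, 10)), rep(0, 10))
  expect_lt(max(abs(batch_norm(z, eps = 1e12))), 1e-4)
})

test_that("mixed pooling interpolates between max and average pooling", {
  set.seed(14)
  m <- matrix(rnorm(36), 6)
  mx <- mixed_pool(m, lambda = 1)
  av <- mixed_pool(m, lambda = 0)
  expect_equal(mx, ref_mixed_pool(m, 1), tolerance = 1e-12)
  expect_equal(av, ref_mixed_pool(m, 0), tolerance = 1e-12)
  for (lam in c(0.25, 0.5, 0.9)) {
    md <- mixed_pool(m, lambda = lam)
    expect_equal(md, ref_mixed_pool(m, lam), tolerance = 1e-12)
    expect_true(all(md <= mx + 1e-12 & md >= av - 1e-12))
  }
})

test_that("XOR fusion has both modes and the annihilation property", {
  set.seed(15)
  a <- array(rnorm(32), c(2, 4, 4, 1))
  b <- array(rnorm(32), c(2, 4, 4, 1))
  expect_equal(pdhand:::xor_fuse(a, b, "soft"), abs(a - b))
  expect_equal(pdhand:::xor_fuse(a, a, "binary"), array(0, dim(a)))
  bin <- pdhand:::xor_fuse(a, b, "binary")
  expect_true(all(bin %in% c(0, 1)))
  expect_error(pdhand:::xor_fuse(a, array(0, c(1, 4, 4, 1))), "unalignable")
})

test_that("ghost modules split channels and undercut dense convolutions", {
  x <- array(rnorm(16 * 8 * 8), c(16, 8, 8, 1))
  spec <- ghost_module_spec(16, 64, ratio = 2, primary_kernel = 3)
  out <- ghost_module(x, spec, seed = 4)
  expect_equal(dim(out)[1], 64)
  expect_equal(dim(out)[2:3], c(8, 8))
  # parameter count oracle: in 16, out 64, k 3, s 2
  ghost_params <- 32 * 16 * 9 + 32 + 32 * 9 + 32
  dense_params <- 64 * 16 * 9 + 64
  expect_equal(ghost_module_params(spec), ghost_params)
  expect_lt(ghost_module_params(spec), dense_params)
  # ratio ~ 1/s plus the depthwise term
  expect_lt(ghost_module_params(spec) / dense_params, 1 / 2 + 0.05)
  # parameter economy holds across configurations with s >= 2
  for (cfg in list(c(8, 32, 2, 1), c(16, 48, 2, 3), c(32, 64, 4, 1))) {
    sp <- ghost_module_spec(cfg[1], cfg[2], ratio = cfg[3],
                            primary_kernel = cfg[4])
    expect_lt(ghost_module_params(sp), cfg[2] * cfg[1] * max(cfg[4], 3)^2 + cfg[2])
  }
  # stride 2 halves spatial dimensions
  out2 <- ghost_module(x, ghost_module_spec(16, 64, stride = 2), seed = 4)
  expect_equal(dim(out2)[2:3], c(4, 4))
  expect_error(ghost_module_spec(16, 63), "divisible")
})

test_that("MDSCM concatenates three XOR-fused branches", {
  x <- matrix(rnorm(16 * 16), 16)
  enc <- list(array(rnorm(32 * 8 * 8), c(32, 8, 8, 1)),
              array(rnorm(64 * 4 * 4), c(64, 4, 4, 1)),
              array(rnorm(128 * 4 * 4), c(128, 4, 4, 1)))
  out <- mdscm_forward(x, enc, seed = 5)
  expect_equal(dim(out), c(32 + 64 + 128, 16, 16, 1))
  expect_true(all(out >= 0))          # soft XOR is an absolute difference
  bad <- enc
  bad[[2]] <- array(0, c(64, 5, 5, 1))
  expect_error(mdscm_forward(x, bad, seed = 5), "resamplable|unalignable")
})

test_that("network forwards are probability-valued, seeded and shape-checked", {
  set.seed(16)
  x <- array(rnorm(16 * 16 * 3), c(1, 16, 16, 3))
  g1 <- ghostnet_forward(x, seed = 7)
  g2 <- ghostnet_forward(x, seed = 7)
  g3 <- ghostnet_forward(x, seed = 8)
  expect_equal(colSums(g1), rep(1, 3), tolerance = 1e-9)
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
  i1 <- improved_linknet_forward(x, seed = 7)
  expect_equal(colSums(i1), rep(1, 3), tolerance = 1e-9)
  expect_identical(i1, improved_linknet_forward(x, seed = 7))
  expect_error(ghostnet_forward(array(rnorm(15 * 15), c(1, 15, 15, 1))),
               "divisible")
  expect_error(improved_linknet_forward(array(rnorm(15 * 15), c(1, 15, 15, 1))),
               "divisible")
})

test_that("a stride-1 ghost bottleneck preserves feature-map shape", {
  x <- array(rnorm(16 * 8 * 8 * 2), c(16, 8, 8, 2))
  model <- pdhand:::ghostnet_init(ghostnet_spec(), seed = 1)
  blk <- list(ci = 16L, out = 16L, exp = 32L, stride = 1L)
  st <- new.env(parent = emptyenv())
  out <- pdhand:::gb_forward(x, blk, model$params, st, "gb1", train = FALSE)
  expect_equal(dim(out$out), dim(x))
})

test_that("analytic gradients agree with finite differences (GhostNet)", {
  set.seed(17)
  x <- array(rnorm(16 * 16 * 4), c(1, 16, 16, 4))
  y <- c(1L, 2L, 1L, 2L)
  model <- pdhand:::ghostnet_init(seed = 3)
  fw <- pdhand:::ghostnet_apply(model, x, train = TRUE)
  ce <- pdhand:::softmax_ce(fw$logits, y)
  gr <- pdhand:::ghostnet_backprop(model, fw$caches, ce$dlogits)
  loss_at <- function(m) {
    m$state <- list2env(as.list(m$state), parent = emptyenv())
    f <- pdhand:::ghostnet_apply(m, x, train = TRUE)
    pdhand:::softmax_ce(f$logits, y)$loss
  }
  for (nm in sample(names(gr), 8)) {
    idx <- sample(length(model$params[[nm]]), 1)
    eps <- 1e-5
    up <- model; up$params[[nm]][idx] <- up$params[[nm]][idx] + eps
    dn <- model; dn$params[[nm]][idx] <- dn$params[[nm]][idx] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(gr[[nm]][idx], num, tolerance = 1e-3)
  }
})

test_that("core layer primitives pass finite-difference checks", {
  set.seed(18)
  x <- array(rnorm(3 * 6 * 6 * 2), c(3, 6, 6, 2))
  W <- array(rnorm(4 * 3 * 3 * 3, sd = 0.3), c(4, 3, 3, 3))
  b <- rnorm(4)
  for (stride in c(1L, 2L)) {
    fw <- pdhand:::conv2d_forward(x, W, b, stride = stride)
    tgt <- array(rnorm(length(fw$out)), dim(fw$out))
    loss <- function(xx, WW, bb)
      sum(pdhand:::conv2d_forward(xx, WW, bb, stride = stride)$out * tgt)
    bk <- pdhand:::conv2d_backward(tgt, W, fw$cache)
    for (probe in 1:5) {
      i <- sample(length(x), 1)
      eps <- 1e-6
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      expect_equal(bk$dx[i], (loss(xp, W, b) - loss(xm, W, b)) / (2 * eps),
                   tolerance = 1e-5)
      j <- sample(length(W), 1)
      Wp <- W; Wp[j] <- Wp[j] + eps
      Wm <- W; Wm[j] <- Wm[j] - eps
      expect_equal(bk$dW[j], (loss(x, Wp, b) - loss(x, Wm, b)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
  # depthwise convolution
  Wd <- array(rnorm(3 * 3 * 3, sd = 0.3), c(3, 3, 3))
  bd <- rnorm(3)
  fw <- pdhand:::dwconv_forward(x, Wd, bd)
  tgt <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- pdhand:::dwconv_backward(tgt, Wd, fw$cache)
  lossd <- function(xx, WW) sum(pdhand:::dwconv_forward(xx, WW, bd)$out * tgt)
  for (probe in 1:5) {
    i <- sample(length(x), 1)
    eps <- 1e-6
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bk$dx[i], (lossd(xp, Wd) - lossd(xm, Wd)) / (2 * eps),
                 tolerance = 1e-5)
  }
  # batch norm (training mode, full backward through the statistics)
  gam <- rnorm(3); bet <- rnorm(3)
  st <- new.env(parent = emptyenv())
  fw <- pdhand:::bn_forward(x, gam, bet, st, "t", train = TRUE)
  tgt <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- pdhand:::bn_backward(tgt, gam, fw$cache)
  lossb <- function(xx) {
    s2 <- new.env(parent = emptyenv())
    sum(pdhand:::bn_forward(xx, gam, bet, s2, "t", train = TRUE)$out * tgt)
  }
  for (probe in 1:5) {
    i <- sample(length(x), 1)
    eps <- 1e-5
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bk$dx[i], (lossb(xp) - lossb(xm)) / (2 * eps), tolerance = 1e-4)
  }
})
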