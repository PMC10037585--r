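test_that("convolution, pooling and upsampling match direct-loop oracles", {
  set.seed(21)
  X <- array(rnorm(8 * 10 * 3 * 2), c(8, 10, 3, 2))
  K <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)); b <- rnorm(4)
  expect_equal(tibiaseg:::cpp_conv2d(X, K, b, 1L, 1L),
               refConv2d(X, K, b, 1, 1), tolerance = 1e-5)
  K1 <- array(rnorm(1 * 1 * 3 * 5), c(1, 1, 3, 5)); b1 <- rnorm(5)
  expect_equal(tibiaseg:::cpp_conv2d(X, K1, b1, 2L, 0L),
               refConv2d(X, K1, b1, 2, 0), tolerance = 1e-5)
  U <- array(rnorm(4 * 6 * 2 * 2), c(4, 6, 2, 2))
  expect_equal(tibiaseg:::cpp_upsample2(U), refUpsample2(U), tolerance = 1e-6)
  P <- array(rnorm(4 * 6 * 2 * 2), c(4, 6, 2, 2))
  mp <- tibiaseg:::cpp_maxpool2(P)
  expect_equal(mp[1, 1, 1, 1], max(P[1:2, 1:2, 1, 1]), tolerance = 1e-6)
  expect_equal(mp[2, 3, 2, 2], max(P[3:4, 5:6, 2, 2]), tolerance = 1e-6)
})

test_that("the attention gate obeys its shape and range contracts", {
  set.seed(8)
  # reference-scale example: gating (N=2, F=128, 16, 32), skip (2, 64, 32, 64)
  x <- array(rnorm(32 * 64 * 64 * 2), c(32, 64, 64, 2))
  g <- array(rnorm(16 * 32 * 128 * 2), c(16, 32, 128, 2))
  p <- attentionGateParams(Cx = 64, Cg = 128, Fint = 128, seed = 1)
  r <- attentionGate(x, g, p)
  expect_equal(dim(r$output), c(32, 64, 64, 2))
  expect_equal(dim(r$alpha), c(32, 64, 1, 2))
  expect_true(all(r$alpha > 0 & r$alpha < 1))
  # gated output equals alpha (*) input, broadcast over channels
  for (ch in c(1, 33, 64))
    expect_equal(r$output[, , ch, ], x[, , ch, ] * r$alpha[, , 1, ],
                 tolerance = 1e-6)
})

test_that("zero gate parameters give a half-open gate", {
  x <- array(rnorm(8 * 16 * 2 * 3), c(8, 16, 2, 3))
  g <- array(rnorm(4 * 8 * 4 * 3), c(4, 8, 4, 3))
  r <- attentionGate(x, g, attentionGateParams(2, 4, 4))
  expect_true(all(r$alpha == 0.5))
  expect_equal(r$output, 0.5 * x, tolerance = 1e-7)
})

test_that("a 1x1 gating case matches hand arithmetic", {
  # scalar signals: x is 2x2 (one channel), g is 1x1
  x <- array(c(1, 2, 3, 4), c(2, 2, 1, 1))
  g <- array(0.5, c(1, 1, 1, 1))
  p <- list(Wx = array(1, c(1, 1, 1, 1)), bx = 0,
            Wg = array(1, c(1, 1, 1, 1)), bg = 0,
            Wpsi = array(1, c(1, 1, 1, 1)), bpsi = 0)
  r <- attentionGate(x, g, p)
  # conv_x picks x[1,1] (stride 2), add g, ReLU, psi, sigmoid
  aHand <- 1 / (1 + exp(-(max(1 * 1 + 1 * 0.5, 0))))
  expect_equal(as.vector(r$alpha), rep(aHand, 4), tolerance = 1e-6)
  expect_equal(as.vector(r$output), as.vector(x) * aHand, tolerance = 1e-6)
})

test_that("the gate agrees with a full R reference implementation", {
  set.seed(31)
  x <- array(rnorm(6 * 8 * 3 * 2), c(6, 8, 3, 2))
  g <- array(rnorm(3 * 4 * 6 * 2), c(3, 4, 6, 2))
  p <- attentionGateParams(3, 6, 6, seed = 4)
  p$bx <- rnorm(6); p$bg <- rnorm(6); p$bpsi <- rnorm(1)
  got <- attentionGate(x, g, p)
  ref <- refAttentionGate(x, g, p)
  expect_equal(got$alpha, ref$alpha, tolerance = 1e-5)
  expect_equal(got$output, ref$output, tolerance = 1e-5)
})

test_that("nonconforming gate shapes raise errors naming the shapes", {
  x <- array(0, c(8, 16, 2, 1))
  gBad <- array(0, c(5, 8, 4, 1))
  expect_error(attentionGate(x, gBad, attentionGateParams(2, 4, 4)), "8,16")
  gN <- array(0, c(4, 8, 4, 2))
  expect_error(attentionGate(x, gN, attentionGateParams(2, 4, 4)), "batch")
})

test_that("network forward conserves shape, bounds and independence", {
  m <- unetCreate(modelConfig(baseFilters = 4), seed = 2)
  batch <- array(runif(32 * 48 * 3), c(32, 48, 3))
  p <- unetForward(m, batch)
  expect_equal(dim(p), c(32, 48, 3))
  expect_true(all(p >= 0 & p <= 1))
  # indivisible input dims fail before computation
  expect_error(unetForward(m, array(0, c(30, 48, 1))), "divisible")
  # per-sample independence (eval mode, running statistics)
  dup <- unetForward(m, batch[, , c(1, 1, 2)])
  expect_identical(dup[, , 1], dup[, , 2])
  expect_equal(dup[, , 3], p[, , 2], tolerance = 1e-5)
  # deterministic initialisation and forward
  m2 <- unetCreate(modelConfig(baseFilters = 4), seed = 2)
  expect_identical(unetForward(m2, batch), p)
  # attention coefficients strictly inside (0, 1) at all four gates
  wa <- unetForward(m, batch, returnAlphas = TRUE)
  expect_length(wa$alphas, 4L)
  for (al in wa$alphas) expect_true(all(al > 0 & al < 1))
})

test_that("forcing alpha to one reduces the network to a plain U-Net", {
  m <- unetCreate(modelConfig(baseFilters = 4), seed = 5)
  batch <- array(runif(32 * 32 * 2), c(32, 32, 2))
  gatesOff <- unetForward(m, batch, gatesOn = FALSE)
  alphaOne <- unetForward(m, batch, alphaOverride = 1)
  expect_equal(gatesOff, alphaOne, tolerance = 1e-7)
  # and the gated path genuinely differs
  expect_gt(max(abs(unetForward(m, batch) - gatesOff)), 0)
})

test_that("stage counting reflects the doubling/halving filter plan", {
  m <- unetCreate(modelConfig(baseFilters = 16), seed = 1)
  st <- countStages(m)
  expect_equal(st$encoderStages, 4L)
  expect_equal(st$decoderStages, 4L)
  expect_equal(st$encoderFilters, c(16, 32, 64, 128))
  expect_equal(st$decoderFilters, c(128, 64, 32, 16))
  expect_equal(st$bottleneckFilters, 256)
  m8 <- unetCreate(modelConfig(baseFilters = 8), seed = 1)
  expect_equal(countStages(m8)$encoderFilters, c(8, 16, 32, 64))
})

test_that("checkpoints round-trip through save/load", {
  m <- unetCreate(modelConfig(baseFilters = 4), seed = 3)
  tmp <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, tmp)
  m2 <- loadModel(tmp)
  batch <- array(runif(16 * 16 * 2), c(16, 16, 2))
  expect_identical(unetForward(m2, batch), unetForward(m, batch))
  expect_equal(m2@config, m@config)
})
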