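test_that("scenario construction balances pairs and conserves scans", {
  mf <- planCohort(paperDefaultCohortSpec())
  sc <- makeScenarios(mf, seed = 1)
  expect_equal(sc$full$n_scans, 107L)
  expect_equal(sc$full$n_pairs, 32L)
  # halves: 53/54 scans over 11/12 mice, pairs split 16/16
  expect_setequal(c(sc$ts1$n_scans, sc$ts2$n_scans), c(53L, 54L))
  expect_setequal(c(length(sc$ts1$mouse_ids), length(sc$ts2$mouse_ids)),
                  c(11L, 12L))
  expect_lte(abs(sc$ts1$n_pairs - sc$ts2$n_pairs), 1L)
  # partition: no loss, no duplication, at mouse level
  expect_setequal(c(sc$ts1$scan_ids, sc$ts2$scan_ids), sc$full$scan_ids)
  expect_length(intersect(sc$ts1$scan_ids, sc$ts2$scan_ids), 0L)
  expect_length(intersect(sc$ts1$mouse_ids, sc$ts2$mouse_ids), 0L)
  # the single-mouse subset: longest series (6 biweekly timepoints, 4 pairs)
  expect_length(sc$tsm$mouse_ids, 1L)
  expect_equal(sc$tsm$n_pairs, 4L)
  tsmRows <- mf[mf$mouse_id == sc$tsm$mouse_ids, ]
  expect_equal(sum(tsmRows$role != "retest"), 6L)
})

test_that("scenario construction handles minimal cohorts", {
  mice <- data.frame(mouse_id = c("a", "b"), group = "diseased",
                     split = "train", n_timepoints = 2L, n_pairs = 1L)
  mf <- planCohort(cohortSpec(rbind(mice,
    data.frame(mouse_id = "c", group = "diseased", split = "val",
               n_timepoints = 1L, n_pairs = 1L))))
  sc <- makeScenarios(mf, seed = 1)
  expect_length(sc$ts1$mouse_ids, 1L)
  expect_length(sc$ts2$mouse_ids, 1L)
  expect_error(makeScenarios(mf[mf$split != "train", ]), "training")
})

test_that("probability thresholding marks strictly-above voxels", {
  g <- VolumeGeometry(c(4L, 2L, 2L), c(1, 1, 1))
  probs <- array(0.4, c(4, 2, 2))          # (H, W, nSlices) along axis 2
  probs[2, 1, 1] <- 0.6; probs[3, 2, 2] <- 0.6
  m <- maskFromProbs(probs, g, axis = 2L, threshold = 0.5)
  expect_equal(sum(maskArray(m)), 2L)
  expect_equal(maskArray(m)[2, 1, 1], 1L)
  expect_equal(maskArray(m)[3, 2, 2], 1L)
  # exact threshold value is background
  expect_equal(sum(maskArray(maskFromProbs(array(0.5, c(4, 2, 2)), g))), 0L)
  expect_equal(sum(maskArray(maskFromProbs(array(0.2, c(4, 2, 2)), g))), 0L)
  expect_equal(sum(maskArray(maskFromProbs(array(0.9, c(4, 2, 2)), g))),
               prod(gridDims(g)))
})

test_that("training drives the loss down and can overfit a tiny fixture", {
  # two 32x32 slices with simple bright-square anatomy
  x <- array(0.05, c(32, 32, 2))
  y <- array(0, c(32, 32, 2))
  x[8:20, 10:22, 1] <- 0.9; y[8:20, 10:22, 1] <- 1
  x[14:26, 4:16, 2] <- 0.9; y[14:26, 4:16, 2] <- 1
  params <- tibiaseg:::cpp_unet_init(4L, 4L, 1L, 7L)
  bm <- matrix(rep(c(1L, 2L), 100), nrow = 2)     # 100 iterations, batch 2
  r1 <- tibiaseg:::cpp_unet_train_epoch(params, x, y, bm[, 1:50, drop = FALSE], 2e-3)
  r2 <- tibiaseg:::cpp_unet_train_epoch(r1$params, x, y, bm[, 51:100, drop = FALSE], 2e-3)
  expect_lt(mean(r2$losses), mean(r1$losses[1:5]))
  expect_lt(r2$losses[50], r1$losses[1])
  # overfit: prediction of its own slice above 95% Jaccard
  probs <- tibiaseg:::cpp_unet_forward(r2$params, x, TRUE, FALSE, NA_real_)$probs
  pred <- probs > 0.5
  ji <- 100 * sum(pred & y == 1) / sum(pred | y == 1)
  expect_gt(ji, 95)
})

test_that("cohort training is reproducible and selects on validation Jaccard", {
  sc <- makeScenarios(microManifest, seed = 1)
  cfg <- trainingConfig(batchSize = 16L, maxEpochs = 2L,
                        learningRate = 2e-3, seed = 3L)
  m1 <- trainUNet(sc$full, microManifest, microDir,
                  model = modelConfig(baseFilters = 4), config = cfg)
  m2 <- trainUNet(sc$full, microManifest, microDir,
                  model = modelConfig(baseFilters = 4), config = cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@params, m2@params)
  expect_equal(nrow(m1@history), 2L)
  expect_true(all(c("epoch", "train_bce", "val_jaccard") %in% names(m1@history)))
  expect_equal(m1@bestEpoch, which.max(m1@history$val_jaccard))
  # prediction returns a mask on the scan geometry
  row <- microManifest[microManifest$split == "test", ][1, ]
  scan <- readMHD(file.path(microDir, row$image_path))
  pm <- predictVolume(m1, scan)
  expect_s4_class(pm, "BinaryMask")
  expect_equal(gridDims(pm), gridDims(scan))
  # evaluateSet produces one metric row per test scan
  ev <- evaluateSet(microManifest, microDir, m1, split = "test")
  expect_equal(nrow(ev), sum(microManifest$split == "test"))
  expect_true(all(c("JI", "VI", "VE", "HD", "seg_mm3", "ref_mm3") %in% names(ev)))
})

test_that("full training beats single-mouse training on held-out mice", {
  # training-set-size effect as a stochastic property over 3 seeds
  sc <- makeScenarios(microManifest, seed = 1)
  mc <- modelConfig(baseFilters = 8)
  jiFull <- c(); jiTsm <- c()
  for (s in 1:3) {
    cfg <- trainingConfig(batchSize = 16L, maxEpochs = 10L,
                          learningRate = 2e-3, seed = s)
    f <- trainUNet(sc$full, microManifest, microDir, mc, cfg)
    t <- trainUNet(sc$tsm, microManifest, microDir, mc, cfg)
    jiFull <- c(jiFull, mean(evaluateSet(microManifest, microDir, f,
                                         split = "test")$JI))
    jiTsm <- c(jiTsm, mean(evaluateSet(microManifest, microDir, t,
                                       split = "test")$JI))
  }
  expect_gte(mean(jiFull), mean(jiTsm))
})

test_that("training input contracts are enforced", {
  sc <- makeScenarios(microManifest, seed = 1)
  emptyScenario <- sc$full
  emptyScenario$scan_ids <- character()
  expect_error(trainUNet(emptyScenario, microManifest, microDir), "empty")
  noVal <- microManifest[microManifest$split != "val", ]
  expect_error(trainUNet(sc$full, noVal, microDir), "validation")
})

test_that("intensity normalisation maps the percentile window to [0,1]", {
  x <- array(stats::rnorm(4096, 5000, 800), c(16, 16, 16))
  n <- normalizeIntensities(ScanVolume(unitGeom(c(16L, 16L, 16L)), x))
  expect_gte(min(n), 0); expect_lte(max(n), 1)
  q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  mid <- (x > q[1]) & (x < q[2])
  expect_equal(n[mid], (x[mid] - q[1]) / (q[2] - q[1]), tolerance = 1e-12)
})
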