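microGeom <- function() VolumeGeometry(c(32L, 16L, 64L), c(0.20, 0.18, 0.38))
microPhantom <- function(seed = 1L, ...)
  phantomSpec(geometry = microGeom(), shaftLengthMM = 16,
              curvature = c(0.35, 0.45), condyleScale = 1.4, seed = seed, ...)

test_that("the default phantom has realistic anatomy", {
  p <- generateTibiaPhantom(phantomSpec(seed = 2))
  v <- maskVolume(p$mask)
  expect_gte(v, 6.5); expect_lte(v, 9.9)
  # single 26-connected component
  ncomp <- tibiaseg:::cpp_label26(as.integer(maskArray(p$mask)),
                                  gridDims(p$mask))
  expect_equal(ncomp, 1L)
  # image within the 14-bit range, brighter inside the marrow than outside
  expect_gte(min(intensities(p$scan)), 0)
  expect_lte(max(intensities(p$scan)), 16383)
  inside <- mean(intensities(p$scan)[maskArray(p$mask) == 1])
  outside <- mean(intensities(p$scan)[maskArray(p$mask) == 0])
  expect_gt(inside, outside)
})

test_that("phantom generation is deterministic and noise-controllable", {
  a <- generateTibiaPhantom(microPhantom(seed = 9))
  b <- generateTibiaPhantom(microPhantom(seed = 9))
  expect_identical(intensities(a$scan), intensities(b$scan))
  expect_identical(maskArray(a$mask), maskArray(b$mask))
  c <- generateTibiaPhantom(microPhantom(seed = 10))
  expect_false(identical(intensities(a$scan), intensities(c$scan)))
  # zero noise: a deep background corner is exactly constant
  q <- generateTibiaPhantom(microPhantom(seed = 9, noiseSigma = 0))
  corner <- intensities(q$scan)[1:3, 1:3, 1:3]
  expect_equal(length(unique(as.vector(corner))), 1L)
})

test_that("volume targeting follows the growth model range", {
  for (tv in c(6.6, 8.0, 9.8)) {
    p <- generateTibiaPhantom(microPhantom(seed = 4, targetVolumeMM3 = tv))
    expect_lt(abs(maskVolume(p$mask) - tv) / tv, 0.06)
  }
  expect_error(generateTibiaPhantom(
    phantomSpec(geometry = VolumeGeometry(c(8L, 6L, 64L), c(0.2, 0.18, 0.38)),
                shaftLengthMM = 16, seed = 1)), "too small")
})

test_that("retest pairs preserve the anatomy volume", {
  # identity perturbation with shared noise reproduces the scan exactly
  pr <- generateRetestPair(microPhantom(seed = 5),
                           retestPerturbation(0, 0, independentNoise = FALSE))
  expect_identical(intensities(pr$test$scan), intensities(pr$retest$scan))
  expect_identical(maskArray(pr$test$mask), maskArray(pr$retest$mask))
  # default perturbation: ground-truth volume drift at most 2%
  drift <- vapply(1:12, function(s) {
    pr <- generateRetestPair(microPhantom(seed = 100 + s))
    v1 <- maskVolume(pr$test$mask); v2 <- maskVolume(pr$retest$mask)
    abs(v2 - v1) / ((v1 + v2) / 2)
  }, 0)
  expect_lte(max(drift), 0.02)
  # transform pushing the anatomy outside the grid is refused
  expect_error(generateRetestPair(microPhantom(seed = 5),
                                  retestPerturbation(0, 40)), "outside")
})

test_that("ground-truth test-retest volumes have sub-1.5% wCV", {
  pairs <- do.call(rbind, lapply(1:13, function(s) {
    pr <- generateRetestPair(microPhantom(seed = 200 + s,
                                          targetVolumeMM3 = stats::runif(1, 6.6, 9.7)))
    data.frame(pair_id = s, test_mm3 = maskVolume(pr$test$mask),
               retest_mm3 = maskVolume(pr$retest$mask))
  }))
  expect_lt(wcv(pairs), 1.5)
})

test_that("the simulated annotator is calibrated and well-behaved", {
  m <- generateTibiaPhantom(microPhantom(seed = 6))$mask
  # identity model
  expect_identical(simulateAnnotator(m, annotatorModel(0, 0)), m)
  # calibrated over-segmentation: mean VE in the observed 10-18% band
  ve <- vapply(1:20, function(s)
    volumeError(simulateAnnotator(m, annotatorModel(0.14, 0.35, seed = s)), m), 0)
  expect_gte(mean(ve), 10); expect_lte(mean(ve), 18)
  # type preservation + determinism
  a1 <- simulateAnnotator(m, annotatorModel(0.1, 0.5, seed = 3))
  a2 <- simulateAnnotator(m, annotatorModel(0.1, 0.5, seed = 3))
  expect_identical(maskArray(a1), maskArray(a2))
  expect_s4_class(a1, "BinaryMask")
  expect_true(all(maskArray(a1) %in% c(0L, 1L)))
  expect_equal(gridDims(a1), gridDims(m))
  # negative bias under-segments on average
  veNeg <- vapply(1:10, function(s)
    volumeError(simulateAnnotator(m, annotatorModel(-0.1, 0.35, seed = s)), m), 0)
  expect_lt(mean(veNeg), 0)
})

test_that("cohort plans reproduce the study census", {
  mf <- planCohort(paperDefaultCohortSpec())
  cen <- cohortCensus(mf)
  expect_equal(cen$n_scans, 157L)
  expect_equal(cen$n_pairs, 49L)
  expect_equal(cen$n_mice, 32L)
  expect_equal(unname(cen$scans), c(107, 17, 33))
  expect_equal(unname(cen$pairs), c(32, 4, 13))
  expect_equal(sum(mf$group == "control" & mf$split == "train"), 21)
  expect_equal(sum(mf$group == "control" & mf$split == "val"), 6)
  expect_equal(sum(mf$group == "control" & mf$split == "test"), 0)
  # deterministic
  expect_identical(mf, planCohort(paperDefaultCohortSpec()))
  # scaled spec: 6 mice x (2 timepoints + 2 retests) = 24 scans, 12 pairs
  cen2 <- cohortCensus(planCohort(tinyCohortSpec()))
  expect_equal(cen2$n_scans, 24L)
  expect_equal(cen2$n_pairs, 12L)
  expect_equal(unname(cen2$scans), c(16, 4, 4))
  # retests are scheduled the day after their test scan
  tt <- mf[!is.na(mf$pair_id), ]
  byPair <- split(tt$timepoint_days, tt$pair_id)
  expect_true(all(vapply(byPair, function(d) diff(sort(d)) == 1, TRUE)))
})

test_that("infeasible cohort schedules are refused", {
  mice <- data.frame(mouse_id = "m1", group = "diseased", split = "train",
                     n_timepoints = 2L, n_pairs = 3L)
  expect_error(cohortSpec(mice), "infeasible")
  mice2 <- data.frame(mouse_id = "m1", group = "control", split = "test",
                      n_timepoints = 2L, n_pairs = 1L)
  expect_error(cohortSpec(mice2), "control")
})

test_that("generated cohorts are deterministic and readable back", {
  # the shared micro cohort fixture: written files match their manifest
  expect_equal(nrow(microManifest), 16L)
  expect_equal(cohortCensus(microManifest)$n_pairs, 8L)
  r1 <- microManifest[1, ]
  sc <- readMHD(file.path(microDir, r1$image_path))
  mk <- readMHD(file.path(microDir, r1$mask_path_EA1))
  expect_s4_class(sc, "ScanVolume")
  expect_equal(gridDims(sc), c(32L, 16L, 64L))
  expect_gt(maskVolume(mk), 5)
  # EA2 masks exist for val/test only
  expect_true(all(is.na(microManifest$mask_path_EA2[microManifest$split == "train"])))
  vt <- microManifest[microManifest$split %in% c("val", "test"), ]
  expect_true(all(file.exists(file.path(microDir, vt$mask_path_EA2))))
  # byte-identical manifest on regeneration with the same seed
  tmp <- withr::local_tempdir()
  generateCohort(microCohortSpec(seed = 11L), tmp)
  expect_identical(readLines(file.path(tmp, "manifest.csv")),
                   readLines(file.path(microDir, "manifest.csv")))
  f <- microManifest$image_path[1]
  expect_identical(tools::md5sum(file.path(tmp, f))[[1]],
                   tools::md5sum(file.path(microDir, f))[[1]])
})
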