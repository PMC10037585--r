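test_that("overlap metrics reproduce hand-computed cases", {
  d <- c(4L, 4L, 2L)
  r <- array(0L, d); r[1:2, 1, 1] <- 1L               # |R| = 2
  s <- array(0L, d); s[2:3, 1, 1] <- 1L               # |S| = 2, overlap 1
  expect_equal(jaccard(maskOf(s), maskOf(r)), 100 / 3, tolerance = 1e-12)
  expect_equal(volumeIntersectionRatio(maskOf(s), maskOf(r)), 50)
  expect_equal(jaccard(maskOf(r), maskOf(r)), 100)
  expect_equal(volumeIntersectionRatio(maskOf(r), maskOf(r)), 100)
  expect_equal(volumeError(maskOf(r), maskOf(r)), 0)
  disj <- array(0L, d); disj[4, 4, 2] <- 1L
  expect_equal(jaccard(maskOf(disj), maskOf(r)), 0)
  sub <- array(0L, d); sub[1, 1, 1] <- 1L             # S subset of R
  expect_equal(volumeIntersectionRatio(maskOf(sub), maskOf(r)), 100)
  # signed volume error: 114 vs 100 voxels -> +14%
  d2 <- c(10L, 10L, 3L)
  r2 <- array(0L, d2); r2[1:100] <- 1L
  s2 <- array(0L, d2); s2[1:114] <- 1L
  expect_equal(volumeError(maskOf(s2), maskOf(r2)), 14)
  empty <- array(0L, d2)
  expect_equal(volumeError(maskOf(empty), maskOf(r2)), -100)
  expect_error(jaccard(maskOf(s), maskOf(array(0L, d))), "empty")
  expect_error(volumeIntersectionRatio(maskOf(empty), maskOf(r2)), "empty")
  g2 <- BinaryMask(unitGeom(c(4L, 4L, 3L)), array(0L, c(4, 4, 3)))
  expect_error(jaccard(maskOf(s), g2), "mismatch")
})

test_that("Hausdorff distance works in physical units and matches brute force", {
  sp <- c(0.09, 0.075, 0.094)
  d <- c(6L, 6L, 6L)
  a <- array(0L, d); a[2, 3, 3] <- 1L
  b <- array(0L, d); b[3, 3, 3] <- 1L      # offset 1 voxel along the 0.09 axis
  expect_equal(hausdorffMM(maskOf(a, sp), maskOf(b, sp)), 0.09)
  expect_equal(hausdorffMM(maskOf(a, sp), maskOf(a, sp)), 0)
  expect_error(hausdorffMM(maskOf(a, sp), maskOf(array(0L, d), sp)), "nonempty")
  set.seed(42)
  for (i in 1:10) {
    s <- randomMask(c(5L, 5L, 5L), 0.1)
    r <- randomMask(c(5L, 5L, 5L), 0.1)
    expect_equal(hausdorffMM(maskOf(s, sp), maskOf(r, sp)),
                 refHausdorff(s, r, sp), tolerance = 1e-12)
  }
})

test_that("the VI/VE/JI identity holds exactly and metrics are consistent", {
  set.seed(7)
  for (i in 1:25) {
    dims <- c(sample(3:16, 1), sample(3:16, 1), sample(3:16, 1))
    s <- randomMask(dims, stats::runif(1, 0.1, 0.5))
    r <- randomMask(dims, stats::runif(1, 0.1, 0.5))
    ms <- maskOf(s); mr <- maskOf(r)
    ji <- jaccard(ms, mr)
    vi <- volumeIntersectionRatio(ms, mr)
    ve <- volumeError(ms, mr)
    if (vi == 0) expect_equal(ji, 0)      # identity needs overlap
    else expect_equal(impliedJaccard(vi, ve), ji, tolerance = 1e-10)
    # jaccard symmetric; VI/VE generally not
    expect_equal(jaccard(mr, ms), ji)
  }
  expect_equal(impliedJaccard(100, 0), 100)
  expect_error(impliedJaccard(0, 0), "vi")
  expect_error(impliedJaccard(50, -100), "ve")
})

test_that("metrics are invariant under simultaneous axis permutation", {
  sp <- c(0.09, 0.075, 0.094)
  set.seed(5)
  s <- randomMask(c(4L, 5L, 6L), 0.3)
  r <- randomMask(c(4L, 5L, 6L), 0.3)
  perm <- c(3, 1, 2)
  s2 <- aperm(s, perm); r2 <- aperm(r, perm); sp2 <- sp[perm]
  expect_equal(jaccard(maskOf(s, sp), maskOf(r, sp)),
               jaccard(maskOf(s2, sp2), maskOf(r2, sp2)))
  expect_equal(volumeError(maskOf(s, sp), maskOf(r, sp)),
               volumeError(maskOf(s2, sp2), maskOf(r2, sp2)))
  expect_equal(hausdorffMM(maskOf(s, sp), maskOf(r, sp)),
               hausdorffMM(maskOf(s2, sp2), maskOf(r2, sp2)), tolerance = 1e-12)
})

test_that("set summaries use arithmetic mean and sample SD", {
  cases <- data.frame(JI = c(80, 90), VI = c(90, 90), VE = c(-5, 5), HD = c(0.2, 0.4))
  sm <- summarizeMetrics(cases)
  expect_equal(sm$mean[sm$metric == "JI"], 85)
  expect_equal(sm$sd[sm$metric == "JI"], sd(c(80, 90)))   # 7.071
  expect_equal(sm$sd[sm$metric == "VI"], 0)
  one <- summarizeMetrics(cases[1, ])
  expect_equal(one$mean[one$metric == "JI"], 80)
  expect_equal(one$sd, rep(0, 4))
  expect_true(isTRUE(attr(one, "degenerate")))
  expect_error(summarizeMetrics(cases[0, ]), "at least one")
})

test_that("scenario comparisons follow the corrected-threshold paired t-test", {
  a <- c(83.1, 84.2, 82.5, 85.0, 83.8, 84.9, 82.2, 83.3, 84.1, 83.0)
  b <- a + c(0.5, -0.2, 0.8, 0.1, 0.9, 0.4, 0.7, -0.1, 0.6, 0.3)
  res <- compareScenarios(a, b)
  # closed-form paired-t oracle
  d <- a - b
  tOracle <- mean(d) / (sd(d) / sqrt(length(d)))
  pOracle <- 2 * stats::pt(-abs(tOracle), df = length(d) - 1)
  expect_equal(res$t, tOracle, tolerance = 1e-9)
  expect_equal(res$p, pOracle, tolerance = 1e-9)
  expect_identical(res$significant, pOracle < 0.009)
  same <- compareScenarios(a, a)
  expect_equal(same$t, 0)
  expect_false(same$significant)
  expect_true(same$degenerate)
  shifted <- compareScenarios(a, a + 2)   # zero-variance nonzero differences
  expect_true(shifted$degenerate)
  expect_true(is.na(shifted$p))
  expect_error(compareScenarios(a, b[-1]), "equal length")
})
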