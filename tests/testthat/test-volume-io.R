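test_that("reference geometry reproduces the scanner layout", {
  g <- refGeometry()
  expect_equal(gridDims(g), c(128L, 64L, 256L))
  # printed voxel volume 6.35e-4 mm^3 at its printed precision
  expect_equal(voxelVolume(g), 0.09 * 0.075 * 0.094)
  expect_lte(abs(voxelVolume(g) - 6.35e-4), 5.001e-7)
  m <- array(0L, dim = gridDims(g)); m[60:70, 30:34, 100:140] <- 1L
  st <- extractSlices(BinaryMask(g, m))
  expect_length(st@slices, 64L)
  expect_equal(dim(st@slices[[1]]), c(128L, 256L))
})

test_that("geometry and mask validity is enforced", {
  expect_error(VolumeGeometry(c(10L, 0L, 5L), c(1, 1, 1)), "dims")
  expect_error(VolumeGeometry(c(10L, 10L, 5L), c(1, -1, 1)), "spacing")
  expect_error(ScanVolume(unitGeom(c(2L, 2L, 2L)), array(NaN, c(2, 2, 2))),
               "finite")
  expect_error(BinaryMask(unitGeom(c(2L, 2L, 2L)), array(2L, c(2, 2, 2))),
               "0 or 1")
  expect_error(BinaryMask(unitGeom(c(3L, 2L, 2L)), array(0L, c(2, 2, 2))),
               "shape")
})

test_that("MHD write/read round trips are exact", {
  tmp <- withr::local_tempdir()
  g <- VolumeGeometry(c(10L, 8L, 6L), c(0.09, 0.075, 0.094))
  m <- array(0L, c(10, 8, 6))
  set.seed(3); m[sample(480, 100)] <- 1L
  bm <- BinaryMask(g, m)
  writeMHD(bm, file.path(tmp, "m.mhd"))
  b2 <- readMHD(file.path(tmp, "m.mhd"))
  expect_s4_class(b2, "BinaryMask")
  expect_identical(maskArray(b2), maskArray(bm))
  expect_equal(spacing(b2), spacing(bm))         # full float precision
  expect_equal(sum(maskArray(b2)), 100)

  # integer-valued scan -> unsigned 16-bit, bit-exact round trip
  iv <- array(sample(0:16383, 480, TRUE), c(10, 8, 6))
  sv <- ScanVolume(g, iv)
  writeMHD(sv, file.path(tmp, "s.mhd"))
  s2 <- readMHD(file.path(tmp, "s.mhd"))
  expect_s4_class(s2, "ScanVolume")
  expect_identical(intensities(s2), intensities(sv))

  # non-integer scan -> float32 on disk
  fv <- ScanVolume(g, array(stats::runif(480), c(10, 8, 6)))
  writeMHD(fv, file.path(tmp, "f.mhd"))
  f2 <- readMHD(file.path(tmp, "f.mhd"))
  expect_equal(intensities(f2), intensities(fv), tolerance = 1e-7)
})

test_that("readMHD parses an externally written header and flags bad input", {
  tmp <- withr::local_tempdir()
  # hand-written MetaImage pair, independent of writeMHD
  vals <- as.integer(c(0:23) * 100)
  writeBin(vals, file.path(tmp, "ext.raw"), size = 2, endian = "little")
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               "ElementSpacing = 0.5 0.25 2",
               "DimSize = 2 3 4", "ElementType = MET_USHORT",
               "ElementDataFile = ext.raw"),
             file.path(tmp, "ext.mhd"))
  v <- readMHD(file.path(tmp, "ext.mhd"))
  expect_equal(gridDims(v), c(2L, 3L, 4L))
  expect_equal(spacing(v), c(0.5, 0.25, 2))
  expect_equal(as.vector(intensities(v)), as.numeric(vals))

  expect_error(readMHD(file.path(tmp, "nope.mhd")), "not found")
  # truncated raw
  writeBin(vals[1:5], file.path(tmp, "tr.raw"), size = 2, endian = "little")
  writeLines(c("NDims = 3", "DimSize = 2 3 4", "ElementType = MET_USHORT",
               "ElementDataFile = tr.raw"), file.path(tmp, "tr.mhd"))
  expect_error(readMHD(file.path(tmp, "tr.mhd")), "truncated")
  # unsupported element type is named in the error
  writeLines(c("NDims = 3", "DimSize = 2 3 4", "ElementType = MET_LONG_LONG",
               "ElementDataFile = ext.raw"), file.path(tmp, "bad.mhd"))
  expect_error(readMHD(file.path(tmp, "bad.mhd")), "MET_LONG_LONG")
  # nonzero values coerced to 1 with a warning when forced to mask
  writeBin(as.integer(c(0, 2, 0, 3)), file.path(tmp, "m2.raw"), size = 1)
  writeLines(c("NDims = 3", "DimSize = 2 2 1", "ElementType = MET_UCHAR",
               "ElementDataFile = m2.raw"), file.path(tmp, "m2.mhd"))
  expect_warning(m2 <- readMHD(file.path(tmp, "m2.mhd"), as = "mask"), "coerced")
  expect_equal(sum(maskArray(m2)), 2)
  # unwritable location
  expect_error(writeMHD(v, file.path(tmp, "no-such-dir", "x.mhd")), "directory")
})

test_that("mask volume is additive and survives slice restacking", {
  g <- VolumeGeometry(c(12L, 6L, 10L), c(0.09, 0.075, 0.094))
  empty <- BinaryMask(g, array(0L, gridDims(g)))
  expect_equal(maskVolume(empty), 0)
  a <- array(0L, gridDims(g)); a[1:5, 1:3, 1:4] <- 1L
  b <- array(0L, gridDims(g)); b[8:12, 4:6, 6:10] <- 1L
  expect_equal(maskVolume(BinaryMask(g, a)) + maskVolume(BinaryMask(g, b)),
               maskVolume(BinaryMask(g, a + b)))
  # worked numbers: 1000 and 10244 voxels at the reference spacing
  expect_equal(1000 * voxelVolume(refGeometry()), 0.6345)
  expect_equal(10244 * voxelVolume(refGeometry()), 6.49982, tolerance = 1e-6)
  bm <- BinaryMask(g, a)
  expect_equal(maskVolume(restack(extractSlices(bm))), maskVolume(bm))
  expect_identical(maskArray(restack(extractSlices(bm))), maskArray(bm))
})

test_that("slice extraction covers all axes and degenerate extents", {
  g1 <- VolumeGeometry(c(5L, 1L, 4L), c(1, 1, 1))
  v <- ScanVolume(g1, array(stats::rnorm(20), c(5, 1, 4)))
  st <- extractSlices(v)               # coronal axis has size 1
  expect_length(st@slices, 1L)
  expect_identical(intensities(restack(st)), intensities(v))
  g2 <- VolumeGeometry(c(4L, 3L, 5L), c(1, 1, 1))
  v2 <- ScanVolume(g2, array(stats::rnorm(60), c(4, 3, 5)))
  for (ax in 1:3) {
    st <- extractSlices(v2, axis = ax)
    expect_length(st@slices, gridDims(g2)[ax])
    expect_identical(intensities(restack(st)), intensities(v2))
  }
})
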