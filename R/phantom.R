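#' @include volume-io.R
NULL

## Run code under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic tibia phantom
#'
#' Parametric model of a murine tibia in a 3D gradient-echo-like volume:
#' a cubic-Bezier centerline running along the third (longitudinal) axis
#' carries a linearly tapering elliptical cross-section with a Gaussian
#' condylar bulge at the proximal (knee) end.  The image shows bright,
#' longitudinally heterogeneous marrow inside a darker cortical rim on a
#' noisy background -- the qualitative appearance of the bone in the
#' scans this emulates.
#'
#' @param geometry a [VolumeGeometry-class]; default [refGeometry()].
#' @param shaftLengthMM shaft length along the longitudinal axis (mm).
#' @param radiusProximal,radiusDistal in-plane (x, y) semi-axes (mm) at
#'   the proximal and distal shaft ends; the taper is linear between them.
#' @param curvature bend amplitudes (mm) of the centerline in x and y.
#' @param condyleScale radius multiplier at the knee (proximal bulge).
#' @param condyleFraction fraction of shaft length over which the bulge
#'   decays.
#' @param rimVoxels cortical rim thickness in in-plane voxels (>= 1).
#' @param rimAttenuation rim intensity as a fraction of mean marrow
#'   intensity (cortical bone is nearly signal-free on gradient echo).
#' @param marrowMean,marrowSD marrow intensity mean and the amplitude of
#'   its slow longitudinal modulation (arbitrary units, 14-bit range).
#' @param backgroundMean background (soft tissue) intensity level.
#' @param noiseSigma additive Gaussian noise SD (magnitude-image
#'   approximation at moderate SNR).
#' @param targetVolumeMM3 desired mask volume; the cross-section radii
#'   are scaled so that the analytic tube volume matches it.  Default 8.0
#'   mm^3, inside the observed 6.5--9.9 mm^3 range of real tibiae.
#' @param seed integer; identical spec + seed give bit-identical output.
#' @return a list of class `"phantomSpec"`.
#' @seealso [generateTibiaPhantom()]
#' @export
phantomSpec <- function(geometry = refGeometry(),
                        shaftLengthMM = 18,
                        radiusProximal = c(0.50, 0.42),
                        radiusDistal = c(0.33, 0.28),
                        curvature = c(0.7, 1.1),
                        condyleScale = 1.6,
                        condyleFraction = 0.12,
                        rimVoxels = 1,
                        rimAttenuation = 0.15,
                        marrowMean = 9000,
                        marrowSD = 1800,
                        backgroundMean = 1800,
                        noiseSigma = 350,
                        targetVolumeMM3 = 8.0,
                        seed = 1L) {
  stopifnot(all(radiusProximal > 0), all(radiusDistal > 0),
            rimVoxels >= 1, noiseSigma >= 0, shaftLengthMM > 0,
            is(geometry, "VolumeGeometry"))
  structure(list(geometry = geometry, shaftLengthMM = shaftLengthMM,
                 radiusProximal = radiusProximal, radiusDistal = radiusDistal,
                 curvature = curvature, condyleScale = condyleScale,
                 condyleFraction = condyleFraction, rimVoxels = rimVoxels,
                 rimAttenuation = rimAttenuation, marrowMean = marrowMean,
                 marrowSD = marrowSD, backgroundMean = backgroundMean,
                 noiseSigma = noiseSigma, targetVolumeMM3 = targetVolumeMM3,
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

## Centerline/radius profile on a fine parameter grid; all seeded draws
## (Bezier control jitter, heterogeneity phases) happen here.
.phantomProfile <- function(spec) {
  withSeed(spec$seed, {
    jit <- stats::runif(4, -0.15, 0.15)
    phases <- stats::runif(2, 0, 2 * pi)
  })
  g <- spec$geometry
  sp <- g@spacing; d <- g@dims
  fovZ <- d[3] * sp[3]
  L <- spec$shaftLengthMM
  if (L >= fovZ * 0.98) stop("geometry too small: shaft length exceeds the field of view")
  z0 <- (fovZ - L) / 2
  ## cubic Bezier control points for the in-plane centerline (x and y)
  bez <- function(t, p) {
    (1 - t)^3 * p[1] + 3 * (1 - t)^2 * t * p[2] +
      3 * (1 - t) * t^2 * p[3] + t^3 * p[4]
  }
  bx <- spec$curvature[1] * (c(0, 0.9, -0.4, 0.1) + jit[1:2][c(1, 2, 1, 2)] * 0.3)
  by <- spec$curvature[2] * (c(0, 0.4, 1.0, 0.2) * (1 + jit[3] * 0.5))
  tgrid <- seq(0, 1, length.out = 512)
  rx <- spec$radiusProximal[1] + tgrid * (spec$radiusDistal[1] - spec$radiusProximal[1])
  ry <- spec$radiusProximal[2] + tgrid * (spec$radiusDistal[2] - spec$radiusProximal[2])
  bulge <- 1 + (spec$condyleScale - 1) * exp(-(tgrid / spec$condyleFraction)^2)
  rx <- rx * bulge; ry <- ry * bulge
  ## scale radii so the analytic tube volume matches the target
  if (is.finite(spec$targetVolumeMM3) && spec$targetVolumeMM3 > 0) {
    v1 <- pi * mean(rx * ry) * L
    s <- sqrt(spec$targetVolumeMM3 / v1)
    rx <- rx * s; ry <- ry * s
  }
  cxr <- d[1] * sp[1] / 2 + bez(tgrid, bx) - mean(bez(tgrid, bx))
  cyr <- d[2] * sp[2] / 2 + bez(tgrid, by) - mean(bez(tgrid, by))
  ## feasibility: anatomy (center +/- radius + margin) must stay in FOV
  marg <- 2 * max(sp[1:2])
  if (any(cxr - rx < marg) || any(cxr + rx > d[1] * sp[1] - marg) ||
      any(cyr - ry < marg) || any(cyr + ry > d[2] * sp[2] - marg))
    stop("geometry too small to contain the tibia shaft")
  list(z0 = z0, L = L, tgrid = tgrid, cx = cxr, cy = cyr, rx = rx, ry = ry,
       phases = phases)
}

## Noise-free phantom: clean intensity field + ground-truth mask.
.phantomClean <- function(spec) {
  g <- spec$geometry
  d <- g@dims; sp <- g@spacing
  pr <- .phantomProfile(spec)
  xv <- (seq_len(d[1]) - 0.5) * sp[1]
  yv <- (seq_len(d[2]) - 0.5) * sp[2]
  zv <- (seq_len(d[3]) - 0.5) * sp[3]
  img <- array(spec$backgroundMean, dim = d)
  msk <- array(0L, dim = d)
  rimMM <- spec$rimVoxels * mean(sp[1:2])
  edge <- 0.7 * mean(sp[1:2])            # soft partial-volume edge width
  rimI <- spec$marrowMean * spec$rimAttenuation
  hetAmp <- spec$marrowSD / spec$marrowMean
  for (k in seq_len(d[3])) {
    t <- (zv[k] - pr$z0) / pr$L
    if (t < 0 || t > 1) next
    ti <- 1 + round(t * 511)
    cx <- pr$cx[ti]; cy <- pr$cy[ti]; rx <- pr$rx[ti]; ry <- pr$ry[ti]
    ex <- ((xv - cx) / rx)^2
    ey <- ((yv - cy) / ry)^2
    e <- sqrt(outer(ex, ey, `+`))
    rEff <- sqrt(rx * ry)
    dOut <- (e - 1) * rEff                       # approx signed distance, mm
    covOut <- pmin(1, pmax(0, 0.5 - dOut / edge))
    ## longitudinal end caps: fade coverage within half a voxel of the ends
    capW <- 0.5 * sp[3]
    capF <- min(1, max(0, 0.5 + min(zv[k] - pr$z0, pr$z0 + pr$L - zv[k]) / capW))
    covOut <- covOut * capF
    rxi <- max(rx - rimMM, 0.25 * rx)
    ryi <- max(ry - rimMM, 0.25 * ry)
    ei <- sqrt(outer(((xv - cx) / rxi)^2, ((yv - cy) / ryi)^2, `+`))
    dIn <- (ei - 1) * sqrt(rxi * ryi)
    covIn <- pmin(1, pmax(0, 0.5 - dIn / edge)) * capF
    het <- 1 + hetAmp * sin(2 * pi * zv[k] / 4.0 + pr$phases[1]) +
      0.4 * hetAmp * sin(2 * pi * zv[k] / 1.3 + pr$phases[2])
    marrowI <- spec$marrowMean * het
    sl <- spec$backgroundMean + covOut * (rimI - spec$backgroundMean) +
      covIn * (marrowI - rimI)
    img[, , k] <- sl
    msk[, , k] <- (covOut >= 0.5) * 1L
  }
  list(img = img, mask = msk)
}

#' Generate a synthetic tibia phantom scan and ground-truth mask
#'
#' @param spec a [phantomSpec()].
#' @return list with elements `scan` ([ScanVolume-class]) and `mask`
#'   ([BinaryMask-class]).  The mask is a single 26-connected component;
#'   identical spec + seed reproduce the output bit-for-bit.
#' @examples
#' p <- generateTibiaPhantom(phantomSpec(seed = 7))
#' maskVolume(p$mask)    # within the realistic 6.5-9.9 mm^3 range
#' @export
generateTibiaPhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  cl <- .phantomClean(spec)
  img <- .addScanNoise(cl$img, spec$noiseSigma, spec$seed + 1000L)
  g <- spec$geometry
  list(scan = ScanVolume(g, img), mask = BinaryMask(g, cl$mask))
}

.addScanNoise <- function(img, sigma, seed) {
  if (sigma > 0) {
    n <- withSeed(seed, stats::rnorm(length(img), 0, sigma))
    img <- img + n
  }
  img <- round(pmin(pmax(img, 0), 16383))
  array(img, dim = dim(img))
}

#' Test-retest perturbation model
#'
#' Rigid repositioning applied to the phantom anatomy for the
#' consecutive-day rescan: a small rotation about the coronal axis and a
#' sub-voxel to few-voxel translation, with (by default) fresh
#' acquisition noise.  The anatomy itself is unchanged, so the
#' ground-truth mask volume changes only through mask re-gridding
#' (nearest-neighbour interpolation), by design under 2%.
#'
#' @param maxRotationDeg maximum rotation magnitude (degrees).
#' @param maxTranslationVoxels maximum translation per axis (voxels).
#' @param independentNoise logical: draw new acquisition noise for the
#'   retest scan (FALSE reuses the identical noise realisation).
#' @return a list of class `"retestPerturbation"`.
#' @export
retestPerturbation <- function(maxRotationDeg = 2,
                               maxTranslationVoxels = 1.5,
                               independentNoise = TRUE) {
  stopifnot(maxRotationDeg >= 0, maxTranslationVoxels >= 0)
  structure(list(maxRotationDeg = maxRotationDeg,
                 maxTranslationVoxels = maxTranslationVoxels,
                 independentNoise = independentNoise),
            class = "retestPerturbation")
}

## Rigid resample: rotation about axis 2 (through the volume centre) plus
## translation (mm).  interp: "linear" for intensities, "nearest" for masks.
.rigidResample <- function(arr, sp, thetaDeg, tMM, interp = "linear", fill = 0) {
  d <- dim(arr)
  th <- thetaDeg * pi / 180
  cx <- d[1] * sp[1] / 2; cy <- d[2] * sp[2] / 2; cz <- d[3] * sp[3] / 2
  xv <- (seq_len(d[1]) - 0.5) * sp[1] - cx
  zv <- (seq_len(d[3]) - 0.5) * sp[3] - cz
  ## inverse mapping: output point -> source point (rotate by -theta, shift by -t)
  xs2 <- outer(xv - tMM[1], zv - tMM[3], function(x, z) cos(th) * x + sin(th) * z) + cx
  zs2 <- outer(xv - tMM[1], zv - tMM[3], function(x, z) -sin(th) * x + cos(th) * z) + cz
  ys <- (seq_len(d[2]) - 0.5) * sp[2] - tMM[2]
  ## continuous voxel coordinates (1-based centres at (i - 0.5) * sp)
  gx <- xs2 / sp[1] + 0.5
  gz <- zs2 / sp[3] + 0.5
  gy <- ys / sp[2] + 0.5
  ## full voxel grids: index order (i, j, k); gx/gz depend on (i, k), gy on j
  ii <- rep(seq_len(d[1]), times = d[2] * d[3])
  jj <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  kk <- rep(seq_len(d[3]), each = d[1] * d[2])
  X <- gx[cbind(ii, kk)]
  Z <- gz[cbind(ii, kk)]
  Y <- gy[jj]
  av <- as.vector(arr)
  at <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    out <- rep(fill, length(ix))
    lin <- (pmin(pmax(ix, 1), d[1])) + d[1] * (pmin(pmax(iy, 1), d[2]) - 1) +
      d[1] * d[2] * (pmin(pmax(iz, 1), d[3]) - 1)
    v <- av[lin]
    out[ok] <- v[ok]
    out
  }
  if (interp == "nearest") {
    res <- at(round(X), round(Y), round(Z))
  } else {
    x0 <- floor(X); y0 <- floor(Y); z0 <- floor(Z)
    fx <- X - x0; fy <- Y - y0; fz <- Z - z0
    res <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
           fx * (1 - fy) * (1 - fz) * at(x0 + 1, y0, z0) +
           (1 - fx) * fy * (1 - fz) * at(x0, y0 + 1, z0) +
           fx * fy * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
           (1 - fx) * (1 - fy) * fz * at(x0, y0, z0 + 1) +
           fx * (1 - fy) * fz * at(x0 + 1, y0, z0 + 1) +
           (1 - fx) * fy * fz * at(x0, y0 + 1, z0 + 1) +
           fx * fy * fz * at(x0 + 1, y0 + 1, z0 + 1)
  }
  array(res, dim = d)
}

#' Generate a consecutive-day test-retest phantom pair
#'
#' The first scan is the phantom of `spec`; the second is the same
#' anatomy after a random rigid repositioning drawn within the
#' perturbation bounds, with fresh noise (unless `independentNoise` is
#' FALSE).  Ground-truth mask volumes of the two scans agree to within
#' 2%, the assumption under which consecutive-day volume differences
#' measure segmentation error only.
#'
#' @param spec a [phantomSpec()].
#' @param perturbation a [retestPerturbation()].
#' @return list with elements `test` and `retest`, each a list
#'   `(scan, mask)` as from [generateTibiaPhantom()].
#' @export
generateRetestPair <- function(spec, perturbation = retestPerturbation()) {
  stopifnot(inherits(spec, "phantomSpec"),
            inherits(perturbation, "retestPerturbation"))
  cl <- .phantomClean(spec)
  g <- spec$geometry; sp <- g@spacing
  prm <- withSeed(spec$seed + 5000L, {
    list(theta = stats::runif(1, -1, 1) * perturbation$maxRotationDeg,
         t = stats::runif(3, -1, 1) * perturbation$maxTranslationVoxels * sp)
  })
  if (perturbation$maxRotationDeg == 0) prm$theta <- 0
  if (perturbation$maxTranslationVoxels == 0) prm$t <- c(0, 0, 0)
  ## feasibility: transformed mask bounding box must stay inside the grid
  bb <- apply(which(cl$mask == 1L, arr.ind = TRUE), 2, range)
  half <- gridDims(g) * sp / 2
  corn <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
  pc <- sweep(sweep(corn, 2, 0.5) , 2, sp, `*`)
  pcc <- sweep(pc, 2, half)
  th <- prm$theta * pi / 180
  rot <- cbind(cos(th) * pcc[, 1] - sin(th) * pcc[, 3], pcc[, 2],
               sin(th) * pcc[, 1] + cos(th) * pcc[, 3])
  moved <- sweep(sweep(rot, 2, half, `+`), 2, prm$t, `+`)
  if (any(moved < 0) || any(moved > rep(2 * half, each = nrow(moved))))
    stop("retest transform pushes the anatomy outside the image grid")
  img2 <- .rigidResample(cl$img, sp, prm$theta, prm$t, "linear",
                         fill = spec$backgroundMean)
  msk2 <- .rigidResample(cl$mask, sp, prm$theta, prm$t, "nearest", fill = 0L)
  noiseSeed1 <- spec$seed + 1000L
  noiseSeed2 <- if (perturbation$independentNoise) spec$seed + 2000L else noiseSeed1
  test <- list(scan = ScanVolume(g, .addScanNoise(cl$img, spec$noiseSigma, noiseSeed1)),
               mask = BinaryMask(g, cl$mask))
  retest <- list(scan = ScanVolume(g, .addScanNoise(img2, spec$noiseSigma, noiseSeed2)),
                 mask = BinaryMask(g, array(as.integer(msk2), dim = gridDims(g))))
  list(test = test, retest = retest)
}

#' Simulated expert annotator
#'
#' Stochastic contouring model applied to a ground-truth mask: a smooth
#' random displacement of the boundary (spatially correlated, emulating
#' the slice-to-slice sweep of a human contour) plus a systematic
#' volume bias.  `volumeBiasFraction = 0.14` reproduces the ~14%
#' over-segmentation observed between the two expert annotators;
#' `boundaryJitterSigma` (in voxel shells) sets the random component and
#' hence the annotator's test-retest variability.
#'
#' @param volumeBiasFraction expected relative volume error of the
#'   annotation (+ = over-segmentation).
#' @param boundaryJitterSigma SD of the correlated boundary displacement,
#'   in voxels.  0 with bias 0 returns the mask unchanged.
#' @param fieldStep correlation grid step of the displacement field
#'   (voxels).
#' @param seed integer RNG seed.
#' @return a list of class `"annotatorModel"`.
#' @export
annotatorModel <- function(volumeBiasFraction = 0, boundaryJitterSigma = 0,
                           fieldStep = 12L, seed = 1L) {
  stopifnot(volumeBiasFraction > -1, boundaryJitterSigma >= 0, fieldStep >= 2)
  structure(list(volumeBiasFraction = volumeBiasFraction,
                 boundaryJitterSigma = boundaryJitterSigma,
                 fieldStep = as.integer(fieldStep), seed = as.integer(seed)),
            class = "annotatorModel")
}

.shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

.dilate6 <- function(a) {
  a | .shift3(a, 1, 0, 0) | .shift3(a, -1, 0, 0) |
    .shift3(a, 0, 1, 0) | .shift3(a, 0, -1, 0) |
    .shift3(a, 0, 0, 1) | .shift3(a, 0, 0, -1)
}
.erode6 <- function(a) !.dilate6(!a)

## Half-integer shell distance from the mask surface: the innermost mask
## layer is -0.5, the first outside layer +0.5, etc.; computed out to
## +/- `depth` shells (deeper voxels keep -Inf/+Inf).
.shellDistance <- function(mask, depth = 3L) {
  m <- mask == 1L
  s <- array(Inf, dim(mask))
  s[m] <- -Inf
  cur <- m
  for (k in seq_len(depth)) {      # outside shells
    nxt <- .dilate6(cur)
    s[nxt & !cur] <- k - 0.5
    cur <- nxt
  }
  cur <- m
  for (k in seq_len(depth)) {      # inside shells
    nxt <- .erode6(cur)
    s[cur & !nxt] <- -(k - 0.5)
    cur <- nxt
  }
  s
}

## Smooth N(0,1)-marginal-by-node random field: iid normals on a coarse
## grid, trilinearly interpolated.  Returns the field and its exact
## per-voxel marginal SD (from the interpolation weights).
.smoothField <- function(d, step, seed) {
  nn <- pmax(2L, ceiling((d - 1) / step) + 1L)
  coarse <- withSeed(seed, array(stats::rnorm(prod(nn)), dim = nn))
  axes <- lapply(1:3, function(a) {
    pos <- (seq_len(d[a]) - 1) / step
    i0 <- pmin(floor(pos) + 1L, nn[a] - 1L)
    f <- pos - (i0 - 1L)
    f <- pmin(pmax(f, 0), 1)
    list(i0 = i0, f = f)
  })
  ii <- rep(seq_len(d[1]), times = d[2] * d[3])
  jj <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  kk <- rep(seq_len(d[3]), each = d[1] * d[2])
  f1 <- axes[[1]]$f[ii]; f2 <- axes[[2]]$f[jj]; f3 <- axes[[3]]$f[kk]
  i1 <- axes[[1]]$i0[ii]; i2 <- axes[[2]]$i0[jj]; i3 <- axes[[3]]$i0[kk]
  cv <- as.vector(coarse)
  lin <- function(a, b, c) a + nn[1] * (b - 1) + nn[1] * nn[2] * (c - 1)
  u <- (1 - f1) * (1 - f2) * (1 - f3) * cv[lin(i1, i2, i3)] +
       f1 * (1 - f2) * (1 - f3) * cv[lin(i1 + 1, i2, i3)] +
       (1 - f1) * f2 * (1 - f3) * cv[lin(i1, i2 + 1, i3)] +
       f1 * f2 * (1 - f3) * cv[lin(i1 + 1, i2 + 1, i3)] +
       (1 - f1) * (1 - f2) * f3 * cv[lin(i1, i2, i3 + 1)] +
       f1 * (1 - f2) * f3 * cv[lin(i1 + 1, i2, i3 + 1)] +
       (1 - f1) * f2 * f3 * cv[lin(i1, i2 + 1, i3 + 1)] +
       f1 * f2 * f3 * cv[lin(i1 + 1, i2 + 1, i3 + 1)]
  sdv <- sqrt((f1^2 + (1 - f1)^2) * (f2^2 + (1 - f2)^2) * (f3^2 + (1 - f3)^2))
  list(u = array(u, dim = d), sd = array(sdv, dim = d))
}

#' Apply a simulated annotator to a ground-truth mask
#'
#' The mask boundary is displaced by a smooth random field plus a bias
#' offset: voxel x (at shell distance s(x) from the true surface) is
#' included iff `s(x) < delta + sigma * u(x)`.  The offset `delta` is
#' calibrated by root-finding so that the expected annotated volume is
#' `(1 + volumeBiasFraction)` times the true volume under the field's
#' marginal distribution, making the expected volume error equal the
#' configured bias.
#'
#' @param mask a [BinaryMask-class] (the ground truth).
#' @param model an [annotatorModel()].
#' @return a [BinaryMask-class] on the same geometry.
#' @export
simulateAnnotator <- function(mask, model) {
  stopifnot(is(mask, "BinaryMask"), inherits(model, "annotatorModel"))
  b <- model$volumeBiasFraction
  sg <- model$boundaryJitterSigma
  if (b == 0 && sg == 0) return(mask)
  m <- mask@labels
  d <- dim(m)
  s <- .shellDistance(m, depth = 3L)
  v0 <- sum(m)
  target <- (1 + b) * v0
  sLevels <- sort(unique(as.vector(s[is.finite(s)])))
  counts <- vapply(sLevels, function(l) sum(s == l), 0)
  nInterior <- sum(is.infinite(s) & s < 0)
  if (sg > 0) {
    fld <- .smoothField(d, model$fieldStep, model$seed)
    sdLevels <- vapply(sLevels, function(l) mean(fld$sd[s == l]), 0)
    expVol <- function(delta)
      nInterior + sum(counts * stats::pnorm((delta - sLevels) / (sg * sdLevels)))
    lo <- min(sLevels) - 1; hi <- max(sLevels) + 1
    tv <- min(max(target, expVol(lo)), expVol(hi))
    delta <- stats::uniroot(function(x) expVol(x) - tv, c(lo, hi), tol = 1e-6)$root
    out <- (s < delta + sg * fld$u) * 1L
  } else {
    ## deterministic: fill whole shells toward the target volume
    cum <- nInterior + cumsum(counts)
    k <- which.min(abs(cum - target))
    delta <- sLevels[k] + 0.5
    out <- (s < delta) * 1L
  }
  BinaryMask(mask@geometry, array(as.integer(out), dim = d))
}
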