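#' @include cohort.R unet.R
NULL

#' Training hyper-parameters
#'
#' @param batchSize slices per batch (default 40).
#' @param maxEpochs training epochs (default 120); one epoch is
#'   `floor(n_slices / batchSize)` iterations (at least 1).
#' @param learningRate Adam learning rate.
#' @param seed RNG seed controlling initialisation and batch sampling;
#'   training is bit-for-bit reproducible under a fixed seed.
#' @param threshold probability threshold for mask prediction.
#' @return list of class `"trainingConfig"`.
#' @export
trainingConfig <- function(batchSize = 40L, maxEpochs = 120L,
                           learningRate = 1e-3, seed = 1L, threshold = 0.5) {
  stopifnot(batchSize >= 1, maxEpochs >= 1, learningRate > 0)
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 learningRate = learningRate, seed = as.integer(seed),
                 threshold = threshold),
            class = "trainingConfig")
}

#' Construct the four training scenarios from a cohort manifest
#'
#' `full` is the whole training split; `ts1`/`ts2` partition the
#' training mice into two halves balanced first on test-retest pairs,
#' then on scans, then on mouse count (partitioning is at the mouse
#' level so no mouse -- and no scan pair -- is split across the halves);
#' `tsm` is the single training mouse with the longest timepoint series
#' (ties broken by most pairs, then lowest mouse id).
#'
#' @param manifest cohort manifest (see [planCohort()]).
#' @param seed seed for the randomised partition search.
#' @return named list of four `"trainingScenario"` objects, each with
#'   `name`, `scan_ids`, `mouse_ids`, `n_scans`, `n_pairs`.
#' @export
makeScenarios <- function(manifest, seed = 1L) {
  tr <- manifest[manifest$split == "train", ]
  if (nrow(tr) == 0L) stop("manifest has no training split")
  mice <- unique(tr$mouse_id)
  if (length(mice) < 2L) stop("need at least 2 training mice to form scenarios")
  perMouse <- do.call(rbind, lapply(mice, function(m) {
    mm <- tr[tr$mouse_id == m, ]
    data.frame(mouse_id = m, scans = nrow(mm), pairs = countPairs(mm),
               timepoints = sum(mm$role != "retest"))
  }))
  if (sum(perMouse$pairs) < 2L) stop("need at least 2 training pairs")
  sel <- .partitionMice(perMouse, seed)
  mk <- function(name, ids) {
    sub <- tr[tr$mouse_id %in% ids, ]
    structure(list(name = name, scan_ids = sub$scan_id, mouse_ids = ids,
                   n_scans = nrow(sub), n_pairs = countPairs(sub)),
              class = "trainingScenario")
  }
  ## longest timeline, then most pairs, then lowest id
  o <- order(-perMouse$timepoints, -perMouse$pairs, perMouse$mouse_id)
  tsmMouse <- perMouse$mouse_id[o[1]]
  list(full = mk("full", mice),
       ts1 = mk("TS1", sel$a),
       ts2 = mk("TS2", sel$b),
       tsm = mk("TSM", tsmMouse))
}

## Mouse-level two-way partition balanced lexicographically on
## (|pair diff| > 1, |scan diff|, |mouse diff|); randomised greedy starts
## with local move/swap refinement.
.partitionMice <- function(pm, seed) {
  n <- nrow(pm)
  key <- function(inA) {
    pa <- sum(pm$pairs[inA]); pb <- sum(pm$pairs[!inA])
    sa <- sum(pm$scans[inA]); sb <- sum(pm$scans[!inA])
    c(max(0, abs(pa - pb) - 1), abs(sa - sb), abs(sum(inA) - sum(!inA)))
  }
  better <- function(k1, k2) {
    for (i in seq_along(k1)) {
      if (k1[i] < k2[i]) return(TRUE)
      if (k1[i] > k2[i]) return(FALSE)
    }
    FALSE
  }
  refine <- function(inA) {
    k <- key(inA)
    repeat {
      improved <- FALSE
      for (i in seq_len(n)) {                     # single moves
        cand <- inA; cand[i] <- !cand[i]
        if (sum(cand) == 0L || sum(cand) == n) next
        kc <- key(cand)
        if (better(kc, k)) { inA <- cand; k <- kc; improved <- TRUE }
      }
      for (i in which(inA)) for (j in which(!inA)) {   # swaps
        cand <- inA; cand[i] <- FALSE; cand[j] <- TRUE
        kc <- key(cand)
        if (better(kc, k)) { inA <- cand; k <- kc; improved <- TRUE }
      }
      if (!improved) return(list(inA = inA, key = k))
    }
  }
  best <- NULL
  withSeed(seed, {
    for (r in 1:25) {
      ord <- if (r == 1) order(-pm$pairs, -pm$scans, pm$mouse_id) else sample.int(n)
      inA <- logical(n)
      pa <- 0; pb <- 0; sa <- 0; sb <- 0; na <- 0; nb <- 0
      for (i in ord) {
        toA <- if (pa != pb) pa < pb else if (sa != sb) sa < sb else na <= nb
        if (toA) { inA[i] <- TRUE; pa <- pa + pm$pairs[i]; sa <- sa + pm$scans[i]; na <- na + 1 }
        else { pb <- pb + pm$pairs[i]; sb <- sb + pm$scans[i]; nb <- nb + 1 }
      }
      res <- refine(inA)
      if (is.null(best) || better(res$key, best$key)) best <- res
    }
  })
  a <- pm$mouse_id[best$inA]; b <- pm$mouse_id[!best$inA]
  if (length(a) > length(b)) list(a = b, b = a) else list(a = a, b = b)
}

## Coronal slicing axis recorded in a manifest (default 2).
manifestAxis <- function(manifest) {
  if ("coronal_axis" %in% names(manifest)) as.integer(manifest$coronal_axis[1])
  else 2L
}

## Load the slices of the listed scans as (H, W, nSlices) arrays of
## normalised intensities and 0/1 labels, plus per-scan slice index map.
.loadSliceData <- function(manifest, scanIds, dataDir, axis = 2L) {
  rows <- manifest[manifest$scan_id %in% scanIds, ]
  if (nrow(rows) == 0L) stop("no matching scans in manifest")
  xs <- list(); ys <- list()
  for (i in seq_len(nrow(rows))) {
    scan <- readMHD(file.path(dataDir, rows$image_path[i]), as = "image")
    mask <- readMHD(file.path(dataDir, rows$mask_path_EA1[i]), as = "mask")
    xs[[i]] <- .sliceArray(normalizeIntensities(scan), axis)
    ys[[i]] <- .sliceArray(mask@labels, axis)
  }
  list(x = .bindSlices(xs), y = .bindSlices(ys), rows = rows)
}

.sliceArray <- function(x, axis = 2L) {
  if (is(x, "ScanVolume")) x <- x@intensities
  d <- dim(x)
  ap <- aperm(x, c(setdiff(1:3, axis), axis))
  array(ap, dim = c(d[setdiff(1:3, axis)], d[axis]))
}

.bindSlices <- function(lst) {
  d <- dim(lst[[1]])
  n <- sum(vapply(lst, function(a) dim(a)[3], 0L))
  out <- array(0, c(d[1], d[2], n))
  at <- 0L
  for (a in lst) {
    k <- dim(a)[3]
    out[, , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}

#' Robust per-volume intensity normalisation
#'
#' Rescales the 1st--99th percentile window of a scan to \[0, 1\]
#' (clipped), making training robust to the 14-bit intensity range and
#' per-scan gain differences.
#'
#' @param scan a [ScanVolume-class] (or numeric array).
#' @return numeric array in \[0, 1\] of the same dimensions.
#' @export
normalizeIntensities <- function(scan) {
  x <- if (is(scan, "ScanVolume")) scan@intensities else scan
  q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Train the attention U-Net on a scenario
#'
#' Slice-wise training: every coronal slice of every scenario scan is an
#' independent sample (background-only slices included); each iteration
#' draws `batchSize` slices uniformly at random; the loss is binary
#' cross-entropy on the sigmoid output.  After every epoch the mean
#' volume-level validation Jaccard is evaluated and the parameters
#' maximising it over epochs are kept (validation-based model
#' selection).
#'
#' @param scenario a `"trainingScenario"` from [makeScenarios()].
#' @param manifest cohort manifest; its `val` split must be nonempty.
#' @param dataDir directory holding the MHD files (defaults to the
#'   manifest's `dir` attribute).
#' @param model [modelConfig()] or an initialised [AttentionUNet-class]
#'   to continue from.
#' @param config a [trainingConfig()].
#' @param axis coronal slicing axis (defaults to the manifest's
#'   `coronal_axis` column, else 2).
#' @param verbose print per-epoch progress.
#' @return a trained [AttentionUNet-class]; `@history` holds per-epoch
#'   mean training BCE and validation Jaccard.
#' @export
trainUNet <- function(scenario, manifest, dataDir = attr(manifest, "dir"),
                      model = modelConfig(), config = trainingConfig(),
                      axis = manifestAxis(manifest), verbose = FALSE) {
  stopifnot(inherits(scenario, "trainingScenario"),
            inherits(config, "trainingConfig"))
  if (length(scenario$scan_ids) == 0L) stop("empty training scenario")
  valRows <- manifest[manifest$split == "val", ]
  if (nrow(valRows) == 0L) stop("validation split is empty")
  tr <- .loadSliceData(manifest, scenario$scan_ids, dataDir, axis)
  valData <- lapply(seq_len(nrow(valRows)), function(i) {
    scan <- readMHD(file.path(dataDir, valRows$image_path[i]), as = "image")
    mask <- readMHD(file.path(dataDir, valRows$mask_path_EA1[i]), as = "mask")
    list(x = .sliceArray(normalizeIntensities(scan), axis), mask = mask)
  })
  net <- if (is(model, "AttentionUNet")) model
         else unetCreate(model, seed = config$seed)
  nSl <- dim(tr$x)[3]
  iters <- max(1L, nSl %/% config$batchSize)
  params <- net@params
  hist <- data.frame(epoch = integer(), train_bce = numeric(),
                     val_jaccard = numeric())
  best <- list(j = -Inf, params = params, epoch = NA_integer_)
  withSeed(config$seed + 17L, {
    for (ep in seq_len(config$maxEpochs)) {
      bm <- matrix(0L, nrow = config$batchSize, ncol = iters)
      for (it in seq_len(iters))
        bm[, it] <- sample.int(nSl, config$batchSize, replace = nSl < config$batchSize)
      res <- cpp_unet_train_epoch(params, tr$x, tr$y, bm,
                                  config$learningRate)
      params <- res$params
      vj <- mean(vapply(valData, function(v) {
        pm <- .predictFromSlices(params, v$x, axis, config$threshold,
                                 config$batchSize, geometry(v$mask))
        jaccard(pm, v$mask)
      }, 0))
      hist <- rbind(hist, data.frame(epoch = ep, train_bce = mean(res$losses),
                                     val_jaccard = vj))
      if (vj > best$j) best <- list(j = vj, params = params, epoch = ep)
      if (verbose)
        message(sprintf("epoch %d: BCE %.4f, val Jaccard %.2f%%",
                        ep, mean(res$losses), vj))
    }
  })
  new("AttentionUNet", config = net@config, params = best$params,
      history = hist, bestEpoch = best$epoch)
}

.predictFromSlices <- function(params, x, axis, threshold, batchSize, geom) {
  n <- dim(x)[3]
  probs <- array(0, dim(x))
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    sub <- x[, , idx, drop = FALSE]
    probs[, , idx] <- cpp_unet_forward(params, sub, TRUE, FALSE, NA_real_)$probs
  }
  maskFromProbs(probs, geom, axis = axis, threshold = threshold)
}

#' Threshold slice probabilities into a 3D mask
#'
#' Foreground iff probability strictly exceeds the threshold (a value
#' exactly at the threshold is background); the slices are restacked
#' along `axis` onto the scan geometry.
#'
#' @param probs array `(H, W, nSlices)` of per-slice probabilities.
#' @param geom target [VolumeGeometry-class].
#' @param axis slicing axis the probabilities were computed along.
#' @param threshold probability cut, default 0.5.
#' @return a [BinaryMask-class].
#' @export
maskFromProbs <- function(probs, geom, axis = 2L, threshold = 0.5) {
  d <- gridDims(geom)
  stopifnot(all(dim(probs) == c(d[setdiff(1:3, axis)], d[axis])))
  lab <- (probs > threshold) * 1L
  inv <- order(c(setdiff(1:3, axis), axis))
  BinaryMask(geom, array(aperm(array(lab, dim(probs)), inv), dim = d))
}

#' Segment a scan with a trained model
#'
#' Per-slice forward passes along the coronal axis, thresholded and
#' restacked into a 3D mask on the scan geometry.
#'
#' @param model a trained [AttentionUNet-class].
#' @param scan a [ScanVolume-class].
#' @param threshold probability threshold (foreground iff p > threshold).
#' @param axis coronal slicing axis.
#' @param batchSize slices per forward batch.
#' @return a [BinaryMask-class].
#' @export
predictVolume <- function(model, scan, threshold = 0.5, axis = 2L,
                          batchSize = 16L) {
  stopifnot(is(model, "AttentionUNet"), is(scan, "ScanVolume"))
  x <- .sliceArray(normalizeIntensities(scan), axis)
  div <- 2^model@config$depth
  if (dim(x)[1] %% div != 0 || dim(x)[2] %% div != 0)
    stop(sprintf("slice dims %d x %d not divisible by 2^depth = %d",
                 dim(x)[1], dim(x)[2], div))
  .predictFromSlices(model@params, x, axis, threshold, batchSize,
                     geometry(scan))
}

#' Evaluate segmentations against a reference over a manifest subset
#'
#' @param manifest cohort manifest.
#' @param dataDir directory with the MHD files.
#' @param model trained [AttentionUNet-class], or NULL to evaluate
#'   stored masks instead (see `predDir`).
#' @param split manifest split to evaluate ("test", "val", "train"),
#'   or NULL for all scans.
#' @param reference which stored mask is the reference (column
#'   `mask_path_EA1` or `mask_path_EA2`).
#' @param predDir with `model = NULL`: a directory of predicted masks
#'   named `<scan_id>.mhd` (or `<scan_id>_mask.mhd`); when also NULL,
#'   the stored second-annotator masks are evaluated.
#' @param threshold,axis passed to [predictVolume()].
#' @return data.frame with one row per scan: `scan_id`, `split`, the
#'   case metrics `JI`, `VI`, `VE`, `HD`, and the segmented and
#'   reference volumes in mm^3.
#' @export
evaluateSet <- function(manifest, dataDir = attr(manifest, "dir"),
                        model = NULL, split = "test",
                        reference = "mask_path_EA1", predDir = NULL,
                        threshold = 0.5, axis = manifestAxis(manifest)) {
  rows <- if (is.null(split)) manifest else manifest[manifest$split %in% split, ]
  if (nrow(rows) == 0L) stop("no scans in the requested split")
  out <- lapply(seq_len(nrow(rows)), function(i) {
    ref <- readMHD(file.path(dataDir, rows[[reference]][i]), as = "mask")
    seg <- if (!is.null(model)) {
      scan <- readMHD(file.path(dataDir, rows$image_path[i]), as = "image")
      predictVolume(model, scan, threshold = threshold, axis = axis)
    } else if (!is.null(predDir)) {
      cand <- file.path(predDir, paste0(rows$scan_id[i], c(".mhd", "_mask.mhd")))
      hit <- cand[file.exists(cand)]
      if (!length(hit)) stop("no predicted mask for ", rows$scan_id[i],
                             " in ", predDir)
      readMHD(hit[1], as = "mask")
    } else {
      readMHD(file.path(dataDir, rows$mask_path_EA2[i]), as = "mask")
    }
    cbind(data.frame(scan_id = rows$scan_id[i], split = rows$split[i]),
          caseMetrics(seg, ref),
          data.frame(seg_mm3 = maskVolume(seg), ref_mm3 = maskVolume(ref)))
  })
  do.call(rbind, out)
}

#' Test-retest volume pairs for a segmentation method
#'
#' Builds the paired-volume table for [wcv()]/[blandAltman()] from a
#' manifest subset, segmenting each member of every complete pair with
#' the supplied model, or reading the stored ground-truth/annotator
#' masks.
#'
#' @param manifest cohort manifest.
#' @param dataDir directory with the MHD files.
#' @param method `"model"` (requires `model`), `"EA1"` (stored reference
#'   masks) or `"EA2"` (stored second-annotator masks).
#' @param model trained [AttentionUNet-class] when `method = "model"`.
#' @param split manifest split, default "test".
#' @param threshold,axis passed to [predictVolume()].
#' @return data.frame with `pair_id`, `method`, `test_mm3`, `retest_mm3`.
#' @export
pairVolumes <- function(manifest, dataDir = attr(manifest, "dir"),
                        method = c("model", "EA1", "EA2"), model = NULL,
                        split = "test", threshold = 0.5,
                        axis = manifestAxis(manifest)) {
  method <- match.arg(method)
  rows <- manifest[manifest$split %in% split & !is.na(manifest$pair_id), ]
  pids <- names(which(table(rows$pair_id) == 2L))
  if (length(pids) == 0L) stop("no complete pairs in the requested split")
  volOf <- function(row) {
    if (method == "model") {
      scan <- readMHD(file.path(dataDir, row$image_path), as = "image")
      maskVolume(predictVolume(model, scan, threshold = threshold, axis = axis))
    } else {
      col <- if (method == "EA1") "mask_path_EA1" else "mask_path_EA2"
      maskVolume(readMHD(file.path(dataDir, row[[col]]), as = "mask"))
    }
  }
  do.call(rbind, lapply(pids, function(p) {
    pr <- rows[rows$pair_id == p, ]
    data.frame(pair_id = p, method = method,
               test_mm3 = volOf(pr[pr$role == "test", ]),
               retest_mm3 = volOf(pr[pr$role == "retest", ]))
  }))
}
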