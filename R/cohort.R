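#' @include phantom.R
NULL

#' Specification of a synthetic longitudinal cohort
#'
#' Describes the mice, their biweekly scan schedules, which timepoints
#' receive a consecutive-day retest, the train/validation/test split, the
#' per-mouse volume growth model and the simulated second annotator.
#'
#' @param mice data.frame with one row per mouse and columns `mouse_id`,
#'   `group` ("diseased"/"control"), `split` ("train"/"val"/"test"),
#'   `n_timepoints` (biweekly scan visits) and `n_pairs` (how many of the
#'   earliest timepoints get a consecutive-day rescan).
#' @param geometry [VolumeGeometry-class] for all scans.
#' @param phantom base [phantomSpec()]; per-scan specs derive from it
#'   (per-mouse anatomy jitter, per-scan volume target and seed).
#' @param perturbation [retestPerturbation()] for the rescans.
#' @param annotator2 [annotatorModel()] used to simulate the second
#'   expert on validation and test scans (the first annotator of the
#'   synthetic cohort is the ground truth itself).
#' @param growth list with `startRangeMM3` (uniform range of the volume
#'   at day 0), `ratePerWeekMM3` (named: diseased, control), `rateSD`
#'   and `capMM3` (volumes saturate at the top of the observed range).
#' @param seed integer master seed; everything downstream derives from it.
#' @return a list of class `"cohortSpec"`.
#' @seealso [paperDefaultCohortSpec()], [tinyCohortSpec()], [planCohort()]
#' @export
cohortSpec <- function(mice,
                       geometry = refGeometry(),
                       phantom = phantomSpec(geometry = geometry),
                       perturbation = retestPerturbation(),
                       annotator2 = annotatorModel(volumeBiasFraction = 0.14,
                                                   boundaryJitterSigma = 0.35),
                       growth = list(startRangeMM3 = c(6.5, 7.0),
                                     ratePerWeekMM3 = c(diseased = 0.5, control = 0.35),
                                     rateSD = 0.05, capMM3 = 9.9),
                       seed = 1L) {
  stopifnot(is.data.frame(mice),
            all(c("mouse_id", "group", "split", "n_timepoints", "n_pairs") %in% names(mice)))
  if (any(mice$n_pairs > mice$n_timepoints))
    stop("infeasible schedule: a mouse has more retest pairs than timepoints")
  if (any(!mice$group %in% c("diseased", "control")) ||
      any(!mice$split %in% c("train", "val", "test")))
    stop("invalid group or split label in mice table")
  if (any(mice$group == "control" & mice$split == "test"))
    stop("control mice may only appear in the train or validation splits")
  if (anyDuplicated(mice$mouse_id)) stop("duplicated mouse_id")
  structure(list(mice = mice, geometry = geometry, phantom = phantom,
                 perturbation = perturbation, annotator2 = annotator2,
                 growth = growth, seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Cohort specification reproducing the full study census
#'
#' 32 mice (26 diseased, 6 controls), 157 scans with 49 consecutive-day
#' test-retest pairs, split by mouse into training (18 diseased + 5
#' controls, 107 scans, 32 pairs), validation (2 diseased + 1 control,
#' 17 scans, 4 pairs) and test (6 diseased, 33 scans, 13 pairs); one
#' training mouse carries a long series of 6 biweekly timepoints with 4
#' pairs (the single-mouse training subset).
#'
#' @param geometry [VolumeGeometry-class], default [refGeometry()].
#' @param seed master seed.
#' @return a `"cohortSpec"`.
#' @export
paperDefaultCohortSpec <- function(geometry = refGeometry(), seed = 1L) {
  mk <- function(prefix, n0, n, group, split, tp, pr)
    data.frame(mouse_id = sprintf("%s%02d", prefix, n0 + seq_len(n) - 1L),
               group = group, split = split, n_timepoints = tp, n_pairs = pr)
  mice <- rbind(
    ## training: 18 diseased (86 scans, 27 pairs) + 5 controls (21 scans, 5 pairs)
    mk("dis", 1L, 1L, "diseased", "train", 6L, 4L),          # long-series mouse
    mk("dis", 2L, 2L, "diseased", "train", 4L, 2L),
    mk("dis", 4L, 4L, "diseased", "train", 3L, 2L),
    mk("dis", 8L, 11L, "diseased", "train", 3L, 1L),
    mk("ctl", 1L, 1L, "control", "train", 4L, 1L),
    mk("ctl", 2L, 4L, "control", "train", 3L, 1L),
    ## validation: 2 diseased (11 scans, 2 pairs) + 1 control (6 scans, 2 pairs)
    mk("dis", 19L, 1L, "diseased", "val", 5L, 1L),
    mk("dis", 20L, 1L, "diseased", "val", 4L, 1L),
    mk("ctl", 6L, 1L, "control", "val", 4L, 2L),
    ## test: 6 diseased (33 scans, 13 pairs)
    mk("dis", 21L, 2L, "diseased", "test", 4L, 3L),
    mk("dis", 23L, 3L, "diseased", "test", 3L, 2L),
    mk("dis", 26L, 1L, "diseased", "test", 3L, 1L))
  cohortSpec(mice, geometry = geometry, seed = seed)
}

#' Small cohort specification for desk-scale experiments
#'
#' Six mice (5 diseased, 1 control) with 2 biweekly timepoints each, both
#' retested: 24 scans, 12 pairs, split 16/4/4 scans (8/2/2 pairs).  Uses
#' a 64 x 32 x 128 grid at 0.10 x 0.09 x 0.19 mm so that tibia volumes
#' stay in the realistic 6.5--9.9 mm^3 range while every stage (training
#' included) runs on a single CPU in minutes.
#'
#' @param seed master seed.
#' @return a `"cohortSpec"`.
#' @export
tinyCohortSpec <- function(seed = 1L) {
  g <- VolumeGeometry(c(64L, 32L, 128L), c(0.10, 0.09, 0.19))
  mice <- data.frame(
    mouse_id = c("dis01", "dis02", "dis03", "ctl01", "dis04", "dis05"),
    group = c("diseased", "diseased", "diseased", "control", "diseased", "diseased"),
    split = c("train", "train", "train", "train", "val", "test"),
    n_timepoints = 2L, n_pairs = 2L)
  cohortSpec(mice, geometry = g,
             phantom = phantomSpec(geometry = g, shaftLengthMM = 17,
                                   curvature = c(0.6, 0.9)),
             seed = seed)
}

#' Smoke-test cohort specification
#'
#' Four mice, 16 scans, 8 pairs on a 32 x 16 x 64 grid: just enough
#' structure (two training mice, one validation, one test, all
#' timepoints paired) to exercise the whole pipeline in seconds.
#'
#' @param seed master seed.
#' @return a `"cohortSpec"`.
#' @export
microCohortSpec <- function(seed = 1L) {
  g <- VolumeGeometry(c(32L, 16L, 64L), c(0.20, 0.18, 0.38))
  mice <- data.frame(
    mouse_id = c("dis01", "dis02", "dis03", "dis04"),
    group = "diseased",
    split = c("train", "train", "val", "test"),
    n_timepoints = 2L, n_pairs = 2L)
  cohortSpec(mice, geometry = g,
             phantom = phantomSpec(geometry = g, shaftLengthMM = 16,
                                   curvature = c(0.35, 0.45),
                                   condyleScale = 1.4),
             seed = seed)
}

## Deterministic per-mouse growth trajectory (volume target per timepoint).
.mouseVolumes <- function(spec, mouseRow, idx) {
  gr <- spec$growth
  withSeed(spec$seed * 1000L + idx, {
    v0 <- stats::runif(1, gr$startRangeMM3[1], gr$startRangeMM3[2])
    rate <- stats::rnorm(1, gr$ratePerWeekMM3[[mouseRow$group]], gr$rateSD)
  })
  days <- (seq_len(mouseRow$n_timepoints) - 1L) * 14L
  pmin(v0 + pmax(rate, 0) * days / 7, gr$capMM3)
}

#' Plan a cohort: build the scan-level manifest without writing volumes
#'
#' Expands a [cohortSpec()] into one manifest row per scan: retest scans
#' are scheduled the day after their paired test scan, file paths and
#' pair ids are assigned deterministically, and the per-scan target tibia
#' volume follows the mouse's growth trajectory.
#'
#' @param spec a `"cohortSpec"`.
#' @return data.frame with columns `scan_id`, `mouse_id`, `group`,
#'   `timepoint_days`, `split`, `pair_id`, `role`
#'   ("test"/"retest"/"unpaired"), `coronal_axis` (slicing axis index),
#'   `image_path`, `mask_path_EA1`, `mask_path_EA2` and
#'   `vol_target_mm3`.
#' @export
planCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  rows <- list()
  for (i in seq_len(nrow(spec$mice))) {
    m <- spec$mice[i, ]
    vols <- .mouseVolumes(spec, m, i)
    hasEA2 <- m$split %in% c("val", "test")
    for (tp in seq_len(m$n_timepoints)) {
      day <- (tp - 1L) * 14L
      paired <- tp <= m$n_pairs
      pid <- if (paired) sprintf("%s_p%02d", m$mouse_id, tp) else NA_character_
      sid <- sprintf("%s_d%03d", m$mouse_id, day)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = sid, mouse_id = m$mouse_id, group = m$group,
        timepoint_days = day, split = m$split, pair_id = pid,
        role = if (paired) "test" else "unpaired",
        coronal_axis = 2L,
        image_path = paste0(sid, ".mhd"),
        mask_path_EA1 = paste0(sid, "_mask.mhd"),
        mask_path_EA2 = if (hasEA2) paste0(sid, "_mask_EA2.mhd") else NA_character_,
        vol_target_mm3 = vols[tp])
      if (paired) {
        sidR <- sprintf("%s_d%03d", m$mouse_id, day + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          scan_id = sidR, mouse_id = m$mouse_id, group = m$group,
          timepoint_days = day + 1L, split = m$split, pair_id = pid,
          role = "retest",
          coronal_axis = 2L,
          image_path = paste0(sidR, ".mhd"),
          mask_path_EA1 = paste0(sidR, "_mask.mhd"),
          mask_path_EA2 = if (hasEA2) paste0(sidR, "_mask_EA2.mhd") else NA_character_,
          vol_target_mm3 = vols[tp])
      }
    }
  }
  do.call(rbind, rows)
}

## Per-scan phantom spec: per-mouse anatomy, per-scan volume target and
## disease-progressing marrow heterogeneity.
.scanPhantomSpec <- function(spec, mouseIdx, scanRow) {
  base <- spec$phantom
  withSeed(spec$seed * 7919L + mouseIdx, {
    curv <- base$curvature * stats::runif(2, 0.8, 1.2)
    shaft <- base$shaftLengthMM * stats::runif(1, 0.96, 1.04)
  })
  weeks <- scanRow$timepoint_days / 7
  hetSD <- base$marrowSD
  if (scanRow$group == "diseased") hetSD <- hetSD * (1 + 0.06 * weeks)
  ps <- base
  ps$curvature <- curv
  ps$shaftLengthMM <- shaft
  ps$marrowSD <- hetSD
  ps$targetVolumeMM3 <- scanRow$vol_target_mm3
  ## anatomy seed fixed per mouse+timepoint; noise seed varies per scan via
  ## generateRetestPair / generateTibiaPhantom internals
  ps$seed <- as.integer((spec$seed * 131L + mouseIdx * 97L +
                           scanRow$timepoint_days) %% .Machine$integer.max)
  ps
}

#' Generate a full synthetic cohort on disk
#'
#' Writes every scan and ground-truth mask as MetaImage pairs, simulates
#' the second annotator on validation/test scans, and writes
#' `manifest.csv` in `outDir`.  Fully deterministic given the spec seed.
#'
#' @param spec a `"cohortSpec"`.
#' @param outDir output directory (created if missing).
#' @param verbose print progress.
#' @return the manifest data.frame (invisibly), with attribute `dir`.
#' @export
generateCohort <- function(spec, outDir, verbose = FALSE) {
  stopifnot(inherits(spec, "cohortSpec"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- planCohort(spec)
  mouseIdx <- stats::setNames(seq_len(nrow(spec$mice)), spec$mice$mouse_id)
  for (i in which(manifest$role != "retest")) {
    row <- manifest[i, ]
    ps <- .scanPhantomSpec(spec, mouseIdx[[row$mouse_id]], row)
    if (row$role == "test") {
      pr <- generateRetestPair(ps, spec$perturbation)
      j <- which(manifest$pair_id == row$pair_id & manifest$role == "retest")
      .writeScanRow(manifest[i, ], pr$test, spec, outDir)
      .writeScanRow(manifest[j, ], pr$retest, spec, outDir)
    } else {
      ph <- generateTibiaPhantom(ps)
      .writeScanRow(manifest[i, ], ph, spec, outDir)
    }
    if (verbose) message("wrote ", row$scan_id)
  }
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "dir") <- outDir
  invisible(manifest)
}

.writeScanRow <- function(row, ph, spec, outDir) {
  writeMHD(ph$scan, file.path(outDir, row$image_path))
  writeMHD(ph$mask, file.path(outDir, row$mask_path_EA1))
  if (!is.na(row$mask_path_EA2)) {
    am <- spec$annotator2
    am$seed <- as.integer((am$seed * 31L +
      sum(utf8ToInt(row$scan_id)) * 101L) %% .Machine$integer.max)
    ea2 <- simulateAnnotator(ph$mask, am)
    writeMHD(ea2, file.path(outDir, row$mask_path_EA2))
  }
  invisible(NULL)
}

#' Read or write a cohort manifest CSV
#'
#' @param path path of the manifest CSV (its directory is recorded in the
#'   `dir` attribute so that the relative image/mask paths resolve).
#' @return data.frame manifest with attribute `dir`.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "mouse_id", "group", "timepoint_days", "split",
            "pair_id", "role", "image_path", "mask_path_EA1")
  miss <- setdiff(need, names(mf))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  attr(mf, "dir") <- dirname(path)
  mf
}

## Number of complete test-retest pairs within a manifest subset.
countPairs <- function(manifest) {
  pid <- manifest$pair_id[!is.na(manifest$pair_id)]
  sum(table(pid) == 2L)
}

#' Summarise a cohort manifest census
#'
#' @param manifest a manifest data.frame from [planCohort()] or
#'   [readManifest()].
#' @return list with `n_scans`, `n_pairs`, `n_mice`, and per-split scan,
#'   pair and mouse counts.
#' @export
cohortCensus <- function(manifest) {
  bySplit <- function(f) vapply(c(train = "train", val = "val", test = "test"),
                                function(s) f(manifest[manifest$split == s, ]), 0)
  list(n_scans = nrow(manifest),
       n_pairs = countPairs(manifest),
       n_mice = length(unique(manifest$mouse_id)),
       scans = bySplit(nrow),
       pairs = bySplit(countPairs),
       mice = bySplit(function(m) length(unique(m$mouse_id))))
}
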