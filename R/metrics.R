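#' @include geometry.R
NULL

.checkPair <- function(seg, ref) {
  stopifnot(is(seg, "BinaryMask"), is(ref, "BinaryMask"))
  if (!all(gridDims(seg) == gridDims(ref)) ||
      !isTRUE(all.equal(spacing(seg), spacing(ref))))
    stop(sprintf("mask geometry mismatch: [%s @ %s] vs [%s @ %s]",
                 paste(gridDims(seg), collapse = "x"),
                 paste(spacing(seg), collapse = ","),
                 paste(gridDims(ref), collapse = "x"),
                 paste(spacing(ref), collapse = ",")))
}

#' Volumetric overlap and distance metrics
#'
#' Per-case accuracy of a segmentation `seg` against a reference `ref`,
#' following the conventions used for tibia-volume evaluation:
#' \describe{
#'   \item{`jaccard()`}{Jaccard index, `100 * |S n R| / |S u R|` (percent).
#'     Symmetric in its arguments.}
#'   \item{`volumeIntersectionRatio()`}{`100 * |S n R| / |S|` (percent):
#'     the fraction of the evaluated segmentation covered by the
#'     reference.  Not symmetric.}
#'   \item{`volumeError()`}{signed `100 * (|S| - |R|) / |R|` (percent);
#'     positive means over-segmentation relative to the reference.}
#'   \item{`hausdorffMM()`}{classical symmetric Hausdorff distance between
#'     the foreground voxel point clouds in physical (mm) coordinates,
#'     `max(h(S->R), h(R->S))` with `h` the directed greatest
#'     nearest-neighbour distance.}
#' }
#' The three volume metrics satisfy the identity checked by
#' [impliedJaccard()] for every mask pair.
#'
#' @param seg,ref [BinaryMask-class] objects on the same geometry.
#' @return numeric scalar (percent, or mm for `hausdorffMM`).
#' @examples
#' g <- VolumeGeometry(c(4L, 4L, 1L), c(1, 1, 1))
#' a <- array(0, c(4, 4, 1)); a[1:2, 1, 1] <- 1
#' b <- array(0, c(4, 4, 1)); b[2:3, 1, 1] <- 1
#' jaccard(BinaryMask(g, a), BinaryMask(g, b))   # 100 * 1/3
#' @export
jaccard <- function(seg, ref) {
  .checkPair(seg, ref)
  s <- seg@labels == 1L; r <- ref@labels == 1L
  if (!any(r)) stop("reference mask is empty")
  u <- sum(s | r)
  100 * sum(s & r) / u
}

#' @rdname jaccard
#' @export
volumeIntersectionRatio <- function(seg, ref) {
  .checkPair(seg, ref)
  s <- seg@labels == 1L; r <- ref@labels == 1L
  ns <- sum(s)
  if (ns == 0L) stop("evaluated segmentation is empty")
  100 * sum(s & r) / ns
}

#' @rdname jaccard
#' @export
volumeError <- function(seg, ref) {
  .checkPair(seg, ref)
  ns <- sum(seg@labels); nr <- sum(ref@labels)
  if (nr == 0L) stop("reference mask is empty")
  100 * (ns - nr) / nr
}

#' @rdname jaccard
#' @export
hausdorffMM <- function(seg, ref) {
  .checkPair(seg, ref)
  cs <- which(seg@labels == 1L, arr.ind = TRUE)
  cr <- which(ref@labels == 1L, arr.ind = TRUE)
  if (nrow(cs) == 0L || nrow(cr) == 0L)
    stop("Hausdorff distance requires two nonempty masks")
  sp <- spacing(seg)
  a <- sweep(cs, 2L, sp, `*`)
  b <- sweep(cr, 2L, sp, `*`)
  cpp_hausdorff(a, b)
}

#' Jaccard index implied by volume intersection ratio and volume error
#'
#' The three volume metrics are algebraically linked: with
#' `v = |S|/|R| = 1 + VE/100` and intersection fraction
#' `i = |S n R|/|R| = (VI/100) * v`, the Jaccard index is
#' `100 * i / (1 + v - i)`.  Used as an internal-consistency check of
#' metric conventions on reported mean values.
#'
#' @param vi volume intersection ratio, percent in (0, 100].
#' @param ve signed volume error, percent, greater than -100.
#' @return implied Jaccard index, percent.
#' @examples
#' impliedJaccard(100, 0)            # 100
#' round(impliedJaccard(94.64, -1.44), 2)   # 88.59
#' @export
impliedJaccard <- function(vi, ve) {
  if (any(vi <= 0 | vi > 100)) stop("'vi' must be in (0, 100]")
  if (any(ve <= -100)) stop("'ve' must be > -100")
  v <- 1 + ve / 100
  i <- (vi / 100) * v
  100 * i / (1 + v - i)
}

#' Compute all per-case metrics for one segmentation/reference pair
#'
#' @param seg,ref [BinaryMask-class] objects on the same geometry.
#' @return a one-row data.frame with columns `JI`, `VI`, `VE` (percent)
#'   and `HD` (mm).
#' @export
caseMetrics <- function(seg, ref) {
  data.frame(JI = jaccard(seg, ref),
             VI = volumeIntersectionRatio(seg, ref),
             VE = volumeError(seg, ref),
             HD = hausdorffMM(seg, ref))
}

#' Aggregate per-case metrics into a mean +/- SD summary
#'
#' Arithmetic mean and sample (n-1) standard deviation of each metric over
#' the cases of a set, the form in which segmentation accuracy is reported
#' per data subset.
#'
#' @param cases data.frame with columns `JI`, `VI`, `VE`, `HD` (one row
#'   per case), e.g. from rbinding [caseMetrics()] results.
#' @return a data.frame with columns `metric`, `mean`, `sd`, `n`;
#'   for a single case `sd` is reported as 0 with attribute
#'   `degenerate = TRUE`.
#' @export
summarizeMetrics <- function(cases) {
  if (!is.data.frame(cases) || nrow(cases) < 1L)
    stop("'cases' must be a data.frame with at least one row")
  cols <- c("JI", "VI", "VE", "HD")
  stopifnot(all(cols %in% names(cases)))
  n <- nrow(cases)
  out <- data.frame(
    metric = cols,
    mean = vapply(cols, function(k) mean(cases[[k]]), 0),
    sd = vapply(cols, function(k) if (n > 1L) stats::sd(cases[[k]]) else 0, 0),
    n = n, row.names = NULL)
  if (n == 1L) attr(out, "degenerate") <- TRUE
  out
}

#' Paired comparison of a metric between two scenarios
#'
#' Two-tailed paired Student's t-test on case-matched metric values from
#' two training scenarios (or a scenario versus an annotator), declared
#' significant below the Bonferroni-corrected threshold.
#'
#' @param a,b equal-length numeric vectors of a per-case metric, paired by
#'   case.
#' @param alphaCorrected significance threshold applied to the raw
#'   p-value; default 0.009, the corrected level used for the
#'   multi-scenario comparison design.
#' @return list with `t`, `p`, `significant`, `degenerate` (TRUE when the
#'   paired differences have zero variance, in which case `t`/`p` are NA
#'   unless all differences are zero, where t = 0, p = 1).
#' @export
compareScenarios <- function(a, b, alphaCorrected = 0.009) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length (case-paired)")
  if (length(a) < 2L) stop("need at least 2 paired cases")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, significant = FALSE, degenerate = TRUE))
    return(list(t = NA_real_, p = NA_real_, significant = NA, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alphaCorrected, degenerate = FALSE)
}
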