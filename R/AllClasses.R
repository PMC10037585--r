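#' @import methods
NULL

#' VolumeGeometry: voxel grid dimensions and physical spacing
#'
#' Couples the integer grid size of a 3D image with its physical voxel
#' spacing in millimetres.  Every metric with physical units (volumes in
#' mm^3, Hausdorff distances in mm) is derived from this object, so it is
#' validated strictly: three dimensions of at least one voxel each, three
#' strictly positive spacings.
#'
#' @slot dims integer(3), voxels along each axis.
#' @slot spacing numeric(3), millimetres per voxel along each axis.
#'
#' @examples
#' g <- VolumeGeometry(c(128L, 64L, 256L), c(0.09, 0.075, 0.094))
#' voxelVolume(g)   # 6.345e-4 mm^3
#' @export
setClass("VolumeGeometry",
  representation(dims = "integer", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@dims) != 3L || anyNA(object@dims) || any(object@dims < 1L))
      msg <- c(msg, "'dims' must be three integers >= 1")
    if (length(object@spacing) != 3L || anyNA(object@spacing) ||
        any(!is.finite(object@spacing)) || any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be three finite positive values (mm)")
    if (length(msg)) msg else TRUE
  })

#' ScanVolume: a 3D grayscale MRI volume with geometry
#'
#' The intensity grid is stored as a numeric 3D array whose dimensions must
#' equal the geometry; values must be finite (gradient-echo magnitude data,
#' nominally 14-bit, i.e. within \[0, 16383\] when synthesised).
#'
#' @slot geometry a [VolumeGeometry-class].
#' @slot intensities numeric 3D array of finite grayscale values.
#' @export
setClass("ScanVolume",
  representation(geometry = "VolumeGeometry", intensities = "array"),
  validity = function(object) {
    d <- dim(object@intensities)
    if (length(d) != 3L || !all(d == object@geometry@dims))
      return("intensity grid shape must equal geometry dims")
    if (!all(is.finite(object@intensities)))
      return("intensities must be finite (no NA/NaN/Inf)")
    TRUE
  })

#' BinaryMask: a 3D \{0,1\} segmentation mask with geometry
#'
#' @slot geometry a [VolumeGeometry-class].
#' @slot labels 3D array over \{0,1\} aligned voxel-for-voxel with the scan
#'   it annotates.
#' @export
setClass("BinaryMask",
  representation(geometry = "VolumeGeometry", labels = "array"),
  validity = function(object) {
    d <- dim(object@labels)
    if (length(d) != 3L || !all(d == object@geometry@dims))
      return("label grid shape must equal geometry dims")
    v <- object@labels
    if (anyNA(v) || !all(v == 0 | v == 1))
      return("labels must be 0 or 1")
    TRUE
  })

#' SliceStack: an ordered stack of 2D slices extracted from a volume
#'
#' Holds the 2D slices of a volume along a designated slicing axis (the
#' coronal axis for this application), in ascending index order, together
#' with the source geometry and source class so that restacking reproduces
#' the original object exactly.
#'
#' @slot slices list of 2D matrices (height x width).
#' @slot sliceAxis integer axis index (1..3) the slices were taken along.
#' @slot geometry the source [VolumeGeometry-class].
#' @slot sourceClass class of the object the stack came from
#'   ("ScanVolume" or "BinaryMask").
#' @export
setClass("SliceStack",
  representation(slices = "list", sliceAxis = "integer",
                 geometry = "VolumeGeometry", sourceClass = "character"),
  validity = function(object) {
    ax <- object@sliceAxis
    if (length(ax) != 1L || ax < 1L || ax > 3L)
      return("sliceAxis must be 1, 2 or 3")
    if (length(object@slices) != object@geometry@dims[ax])
      return("slice count must equal the geometry extent along sliceAxis")
    pd <- object@geometry@dims[-ax]
    ok <- vapply(object@slices, function(s)
      is.matrix(s) && all(dim(s) == pd), logical(1))
    if (!all(ok)) return("every slice must be a matrix of the in-plane dims")
    if (!object@sourceClass %in% c("ScanVolume", "BinaryMask"))
      return("sourceClass must be 'ScanVolume' or 'BinaryMask'")
    TRUE
  })

#' AttentionUNet: a trained or initialised attention-gated U-Net
#'
#' Wraps the network configuration, the flat parameter list (convolution
#' kernels, batch-norm statistics, attention-gate weights) and, after
#' training, the optimiser state and per-epoch history.
#'
#' @slot config named list: `baseFilters`, `depth`, `inChannels`,
#'   `bilinearUpsampling`.
#' @slot params named list of numeric arrays (see [unetCreate()]).
#' @slot history data.frame of per-epoch training loss and validation
#'   Jaccard (empty until trained).
#' @slot bestEpoch integer, epoch of the selected checkpoint (NA before
#'   training).
#' @export
setClass("AttentionUNet",
  representation(config = "list", params = "list",
                 history = "data.frame", bestEpoch = "integer"))
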