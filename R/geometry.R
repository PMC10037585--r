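#' @include AllGenerics.R
NULL

#' Construct a VolumeGeometry
#'
#' @param dims integer(3): voxels along each axis (x, y, z in storage
#'   order; the first index varies fastest in the raw file).
#' @param spacing numeric(3): millimetres per voxel along each axis.
#' @return a validated [VolumeGeometry-class].
#' @examples
#' refGeometry()                 # the reference 128 x 64 x 256 layout
#' voxelVolume(refGeometry())    # 6.345e-4 mm^3 (prints as 6.35e-4 at 3 s.f.)
#' @export
VolumeGeometry <- function(dims, spacing) {
  new("VolumeGeometry", dims = as.integer(dims), spacing = as.numeric(spacing))
}

#' Reference scanner geometry
#'
#' The 3D gradient-echo layout used throughout: 128 x 64 x 256 voxels at
#' 0.09 x 0.075 x 0.094 mm, voxel volume 6.345e-4 mm^3.  Axis 2 (64
#' voxels) is the coronal slicing axis, so each scan yields 64 coronal
#' slices of 128 x 256.
#' @return a [VolumeGeometry-class].
#' @export
refGeometry <- function() VolumeGeometry(c(128L, 64L, 256L), c(0.09, 0.075, 0.094))

#' Construct a ScanVolume
#' @param geometry a [VolumeGeometry-class].
#' @param intensities numeric 3D array matching the geometry dims.
#' @return a validated [ScanVolume-class].
#' @export
ScanVolume <- function(geometry, intensities) {
  storage.mode(intensities) <- "double"
  new("ScanVolume", geometry = geometry, intensities = intensities)
}

#' Construct a BinaryMask
#' @param geometry a [VolumeGeometry-class].
#' @param labels 3D array over \{0,1\} matching the geometry dims.
#' @return a validated [BinaryMask-class].
#' @export
BinaryMask <- function(geometry, labels) {
  storage.mode(labels) <- "integer"
  new("BinaryMask", geometry = geometry, labels = labels)
}

#' @rdname geometry-accessors
setMethod("geometry", "VolumeGeometry", function(x) x)
#' @rdname geometry-accessors
setMethod("geometry", "ScanVolume", function(x) x@geometry)
#' @rdname geometry-accessors
setMethod("geometry", "BinaryMask", function(x) x@geometry)
#' @rdname geometry-accessors
setMethod("geometry", "SliceStack", function(x) x@geometry)

#' @rdname geometry-accessors
setMethod("gridDims", "VolumeGeometry", function(x) x@dims)
#' @rdname geometry-accessors
setMethod("gridDims", "ANY", function(x) geometry(x)@dims)

#' @rdname geometry-accessors
setMethod("spacing", "VolumeGeometry", function(x) x@spacing)
#' @rdname geometry-accessors
setMethod("spacing", "ANY", function(x) geometry(x)@spacing)

#' @rdname geometry-accessors
setMethod("voxelVolume", "VolumeGeometry", function(x) prod(x@spacing))
#' @rdname geometry-accessors
setMethod("voxelVolume", "ANY", function(x) prod(geometry(x)@spacing))

#' @rdname geometry-accessors
setMethod("intensities", "ScanVolume", function(x) x@intensities)
#' @rdname geometry-accessors
setMethod("maskArray", "BinaryMask", function(x) x@labels)

#' @rdname maskVolume
setMethod("maskVolume", "BinaryMask", function(mask)
  sum(mask@labels) * prod(mask@geometry@spacing))

setMethod("show", "VolumeGeometry", function(object) {
  cat(sprintf("VolumeGeometry: %s voxels @ %s mm (voxel %.4g mm^3)\n",
              paste(object@dims, collapse = " x "),
              paste(signif(object@spacing, 4), collapse = " x "),
              prod(object@spacing)))
})

setMethod("show", "ScanVolume", function(object) {
  r <- range(object@intensities)
  cat(sprintf("ScanVolume: %s voxels @ %s mm, intensity range [%.4g, %.4g]\n",
              paste(object@geometry@dims, collapse = " x "),
              paste(signif(object@geometry@spacing, 4), collapse = " x "),
              r[1], r[2]))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %s voxels @ %s mm, %d foreground (%.4g mm^3)\n",
              paste(object@geometry@dims, collapse = " x "),
              paste(signif(object@geometry@spacing, 4), collapse = " x "),
              sum(object@labels), maskVolume(object)))
})

setMethod("show", "SliceStack", function(object) {
  pd <- object@geometry@dims[-object@sliceAxis]
  cat(sprintf("SliceStack: %d slices of %d x %d along axis %d (from %s)\n",
              length(object@slices), pd[1], pd[2], object@sliceAxis,
              object@sourceClass))
})

sameGeometry <- function(a, b) {
  ga <- geometry(a); gb <- geometry(b)
  all(ga@dims == gb@dims) && isTRUE(all.equal(ga@spacing, gb@spacing))
}
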