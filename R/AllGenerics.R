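#' @include AllClasses.R
NULL

#' Accessors for volume geometry and grids
#'
#' `geometry()` returns the [VolumeGeometry-class] of an image object;
#' `gridDims()` and `spacing()` return its integer dimensions and voxel
#' spacing (mm); `voxelVolume()` the physical volume of one voxel in mm^3;
#' `intensities()` and `labels()` the underlying 3D arrays.
#'
#' @param x a [VolumeGeometry-class], [ScanVolume-class], [BinaryMask-class]
#'   or [SliceStack-class].
#' @return See individual descriptions.
#' @name geometry-accessors
#' @aliases geometry gridDims spacing voxelVolume intensities maskArray
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname geometry-accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname geometry-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname geometry-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname geometry-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname geometry-accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Physical volume of a binary mask
#'
#' Number of foreground voxels times the voxel volume, in mm^3.  Additive
#' over disjoint masks and invariant under slice extraction/restacking.
#'
#' @param mask a [BinaryMask-class].
#' @return numeric scalar, mm^3.
#' @examples
#' g <- VolumeGeometry(c(10L, 10L, 10L), c(0.09, 0.075, 0.094))
#' m <- array(0, c(10, 10, 10)); m[1:10, 1, 1] <- 1
#' maskVolume(BinaryMask(g, m))   # 10 * 6.345e-4
#' @export
setGeneric("maskVolume", function(mask) standardGeneric("maskVolume"))

#' Write a volume or mask as a MetaImage (.mhd/.raw) pair
#'
#' @param x a [ScanVolume-class] or [BinaryMask-class].
#' @param path path of the `.mhd` header to write; the raw data file is
#'   written next to it with the same stem.
#' @param elementType on-disk element type; masks are always written
#'   `MET_UCHAR`, scans default to `MET_USHORT` when integer-valued in
#'   \[0, 65535\] and `MET_FLOAT` otherwise.
#' @return invisibly, the header path.
#' @export
setGeneric("writeMHD", function(x, path, elementType = NULL) standardGeneric("writeMHD"))

#' Extract and restack 2D slices along the coronal axis
#'
#' `extractSlices()` decomposes a 3D volume into its ordered 2D slices
#' along `axis` (by convention axis 2, the coronal axis of the reference
#' 128 x 64 x 256 layout, giving 64 slices of 128 x 256).  `restack()` is
#' its exact inverse.
#'
#' @param x a [ScanVolume-class], [BinaryMask-class] or [SliceStack-class].
#' @param axis integer slicing axis, default 2 (coronal).
#' @return `extractSlices()`: a [SliceStack-class]; `restack()`: an object
#'   of the stack's source class.
#' @export
setGeneric("extractSlices", function(x, axis = 2L) standardGeneric("extractSlices"))

#' @rdname extractSlices
#' @export
setGeneric("restack", function(x) standardGeneric("restack"))
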