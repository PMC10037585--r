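#' @include geometry.R
NULL

## MetaImage element types <-> readBin/writeBin descriptors.
.mhdTypes <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE, mode = "integer"),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE,  mode = "integer"),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE, mode = "integer"),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE,  mode = "integer"),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE,  mode = "integer"),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE,  mode = "integer"),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE,  mode = "double"),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE,  mode = "double"))

.parseMhdHeader <- function(path) {
  if (!file.exists(path)) stop("MHD header not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed MHD header line: ", lines[which(bad)[1]])
  keys <- tolower(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  stats::setNames(as.list(vals), keys)
}

#' Read a MetaImage (.mhd/.raw) volume or mask
#'
#' Parses the plain-text MetaImage header, reads the referenced raw data
#' file and returns a [ScanVolume-class] or [BinaryMask-class] with the
#' header's dimensions and voxel spacing.  Values are bit-exact with the
#' stored element type.
#'
#' @param path path to the `.mhd` header.
#' @param as `"auto"` (default): return a [BinaryMask-class] when the
#'   element type is `MET_UCHAR` and all values are in \{0,1\}, else a
#'   [ScanVolume-class]; `"image"` or `"mask"` force the class.  Forcing
#'   `"mask"` coerces any nonzero value to 1 with a warning.
#' @return a [ScanVolume-class] or [BinaryMask-class].
#' @seealso [writeMHD()]
#' @export
readMHD <- function(path, as = c("auto", "image", "mask")) {
  as <- match.arg(as)
  h <- .parseMhdHeader(path)
  need <- c("ndims", "dimsize", "elementtype", "elementdatafile")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("MHD header missing field(s): ", paste(miss, collapse = ", "))
  if (as.integer(h$ndims) != 3L) stop("only NDims = 3 is supported")
  if (identical(tolower(h$compresseddata %||% "false"), "true"))
    stop("compressed MetaImage data is not supported")
  dims <- as.integer(strsplit(h$dimsize, "\\s+")[[1]])
  spc <- h$elementspacing %||% h$elementsize %||% "1 1 1"
  spc <- as.numeric(strsplit(spc, "\\s+")[[1]])
  if (length(dims) != 3L || length(spc) != 3L)
    stop("DimSize/ElementSpacing must have 3 entries")
  et <- toupper(h$elementtype)
  tp <- .mhdTypes[[et]]
  if (is.null(tp)) stop("unsupported MetaImage element type: ", et)
  msb <- identical(tolower(h$binarydatabyteordermsb %||%
                           h$elementbyteordermsb %||% "false"), "true")
  rawPath <- h$elementdatafile
  if (identical(toupper(rawPath), "LOCAL"))
    stop("ElementDataFile = LOCAL is not supported")
  if (!grepl("^(/|[A-Za-z]:)", rawPath))
    rawPath <- file.path(dirname(path), rawPath)
  if (!file.exists(rawPath)) stop("raw data file not found: ", rawPath)
  n <- prod(dims)
  expect <- as.numeric(n) * tp$size
  if (file.info(rawPath)$size < expect)
    stop(sprintf("raw file truncated: %s has %d bytes, need %.0f",
                 rawPath, file.info(rawPath)$size, expect))
  con <- file(rawPath, "rb"); on.exit(close(con))
  vals <- readBin(con, what = tp$what, n = n, size = tp$size,
                  signed = tp$signed, endian = if (msb) "big" else "little")
  if (length(vals) != n) stop("raw file truncated while reading: ", rawPath)
  arr <- array(as.double(vals), dim = dims)
  geom <- VolumeGeometry(dims, spc)
  isMaskLike <- identical(et, "MET_UCHAR") && all(arr %in% c(0, 1))
  if (as == "mask" || (as == "auto" && isMaskLike)) {
    if (any(!arr %in% c(0, 1))) {
      warning("nonzero mask values coerced to 1 when reading ", path)
      arr <- (arr != 0) + 0L
    }
    BinaryMask(geom, arr)
  } else {
    ScanVolume(geom, arr)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeMhdPair <- function(arr, geom, path, elementType) {
  tp <- .mhdTypes[[elementType]]
  if (is.null(tp)) stop("unsupported MetaImage element type: ", elementType)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  stem <- sub("\\.mhd$", "", basename(path), ignore.case = TRUE)
  rawName <- paste0(stem, ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    "Offset = 0 0 0",
    paste("ElementSpacing =", paste(format(geom@spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(geom@dims, collapse = " ")),
    paste("ElementType =", elementType),
    paste("ElementDataFile =", rawName))
  ok <- tryCatch({
    writeLines(header, path)
    con <- file(file.path(dir, rawName), "wb")
    on.exit(close(con), add = TRUE)
    if (tp$what == "integer") {
      writeBin(as.integer(arr), con, size = tp$size, endian = "little")
    } else {
      writeBin(as.double(arr), con, size = tp$size, endian = "little")
    }
    TRUE
  }, error = function(e) stop("failed to write MetaImage pair at ", path,
                              ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname writeMHD
setMethod("writeMHD", "ScanVolume", function(x, path, elementType = NULL) {
  validObject(x)
  arr <- x@intensities
  if (is.null(elementType)) {
    isInt <- all(arr == round(arr)) && min(arr) >= 0 && max(arr) <= 65535
    elementType <- if (isInt) "MET_USHORT" else "MET_FLOAT"
  }
  .writeMhdPair(arr, x@geometry, path, elementType)
})

#' @rdname writeMHD
setMethod("writeMHD", "BinaryMask", function(x, path, elementType = NULL) {
  validObject(x)
  .writeMhdPair(x@labels, x@geometry, path, "MET_UCHAR")
})

#' @rdname extractSlices
setMethod("extractSlices", "ScanVolume", function(x, axis = 2L) {
  .extract(x@intensities, x@geometry, as.integer(axis), "ScanVolume")
})

#' @rdname extractSlices
setMethod("extractSlices", "BinaryMask", function(x, axis = 2L) {
  .extract(x@labels, x@geometry, as.integer(axis), "BinaryMask")
})

.extract <- function(arr, geom, axis, cls) {
  stopifnot(axis %in% 1:3)
  n <- geom@dims[axis]
  idx <- list(quote(expr =), quote(expr =), quote(expr =))
  slices <- vector("list", n)
  for (i in seq_len(n)) {
    idx[[axis]] <- i
    slices[[i]] <- do.call(`[`, c(list(arr), idx, drop = TRUE))
  }
  new("SliceStack", slices = slices, sliceAxis = axis,
      geometry = geom, sourceClass = cls)
}

#' @rdname extractSlices
setMethod("restack", "SliceStack", function(x) {
  d <- x@geometry@dims
  arr <- array(0, dim = d)
  idx <- list(quote(expr =), quote(expr =), quote(expr =))
  for (i in seq_along(x@slices)) {
    idx[[x@sliceAxis]] <- i
    arr <- do.call(`[<-`, c(list(arr), idx, list(x@slices[[i]])))
  }
  if (x@sourceClass == "BinaryMask") BinaryMask(x@geometry, arr)
  else ScanVolume(x@geometry, arr)
})
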