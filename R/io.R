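## Volume and projection I/O: NIfTI (via RNifti) for interoperability and
## a raw little-endian float32 + JSON sidecar dialect for zero-surprise
## debugging.  The sidecar records shape, spacing, dtype and byte order
## (and, for projections, the geometry and angle table).

.isNiftiPath <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Write / read a volume
#'
#' \code{writeVolume} writes NIfTI when \code{path} ends in
#' \code{.nii}/\code{.nii.gz}, otherwise raw little-endian float32 at
#' \code{<path>.raw} with a JSON sidecar \code{<path>.json} (fields
#' \code{shape} in (x, y, z) order, \code{spacingCm}, \code{dtype},
#' \code{byteOrder}). \code{readVolume} inverts either format; the round
#' trip is lossless at float32 precision.
#'
#' @param vol a [SpectVolume-class].
#' @param path file path (NIfTI) or basename (raw + sidecar).
#' @return \code{writeVolume}: the path, invisibly; \code{readVolume}:
#'   a [SpectVolume-class].
#' @export
writeVolume <- function(vol, path) {
  if (.isNiftiPath(path)) {
    arr <- vol@data
    attr(arr, "pixdim") <- vol@spacing
    img <- RNifti::asNifti(arr, datatype = "float")
    RNifti::writeNifti(img, path)
  } else {
    meta <- list(shape = dim(vol@data), spacingCm = vol@spacing,
      dtype = "float32", byteOrder = "little")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
      digits = NA)
    con <- file(paste0(path, ".raw"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol@data), con, size = 4L, endian = "little")
  }
  invisible(path)
}

.readSidecar <- function(path, required) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) stop("missing sidecar file: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in required)
    if (is.null(meta[[f]]) || length(meta[[f]]) == 0L)
      stop("sidecar ", sc, " is missing required field '", f, "'",
        call. = FALSE)
  dtype <- unlist(meta$dtype)
  if (length(dtype) != 1L || dtype != "float32")
    stop("sidecar field 'dtype' must be \"float32\", got '",
      paste(dtype, collapse = ","), "'", call. = FALSE)
  byteOrder <- unlist(meta$byteOrder)
  if (length(byteOrder) != 1L || byteOrder != "little")
    stop("sidecar field 'byteOrder' must be \"little\", got '",
      paste(byteOrder, collapse = ","), "'", call. = FALSE)
  meta
}

.readRawArray <- function(path, shape) {
  raw <- paste0(path, ".raw")
  if (!file.exists(raw)) stop("missing raw file: ", raw, call. = FALSE)
  n <- prod(shape)
  con <- file(raw, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(v) != n)
    stop("raw file ", raw, " holds ", length(v),
      " values but sidecar field 'shape' implies ", n, call. = FALSE)
  array(v, shape)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (.isNiftiPath(path)) {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:3]
    arr <- array(as.numeric(img), dim(img)[1:3])
    return(new("SpectVolume", data = arr, spacing = spacing))
  }
  meta <- .readSidecar(path, c("shape", "spacingCm", "dtype", "byteOrder"))
  new("SpectVolume", data = .readRawArray(path, unlist(meta$shape)),
    spacing = unlist(meta$spacingCm))
}

#' Write / read a projection set (raw + sidecar)
#'
#' Raw little-endian float32 with a JSON sidecar carrying the array shape
#' (bin, row, angle), the angle table, and the acquisition geometry.
#'
#' @param proj a [ProjectionSet-class].
#' @param path basename; writes \code{<path>.raw} and \code{<path>.json}.
#' @return \code{writeProjections}: the path, invisibly;
#'   \code{readProjections}: a [ProjectionSet-class].
#' @export
writeProjections <- function(proj, path) {
  g <- proj@geometry
  meta <- list(shape = dim(proj@data), dtype = "float32",
    byteOrder = "little", anglesDeg = proj@anglesDeg,
    geometry = list(nAngles = g@nAngles,
      angularRangeDeg = g@angularRangeDeg,
      orbitRadiusCm = g@orbitRadiusCm, detectorBins = g@detectorBins,
      detectorRows = g@detectorRows, binSizeCm = g@binSizeCm,
      startAngleDeg = g@startAngleDeg),
    metadata = proj@metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
    digits = NA)
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(proj@data), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname writeProjections
#' @export
readProjections <- function(path) {
  meta <- .readSidecar(path,
    c("shape", "dtype", "byteOrder", "anglesDeg", "geometry"))
  gm <- meta$geometry
  for (f in c("nAngles", "orbitRadiusCm", "detectorBins", "detectorRows",
      "binSizeCm"))
    if (is.null(gm[[f]]))
      stop("sidecar geometry is missing required field '", f, "'",
        call. = FALSE)
  geom <- acquisitionGeometry(nAngles = gm$nAngles,
    angularRangeDeg = gm$angularRangeDeg %||% 360,
    orbitRadiusCm = gm$orbitRadiusCm, detectorBins = gm$detectorBins,
    detectorRows = gm$detectorRows, binSizeCm = gm$binSizeCm,
    startAngleDeg = gm$startAngleDeg %||% 0)
  arr <- .readRawArray(path, unlist(meta$shape))
  projectionSet(arr, geom, anglesDeg = unlist(meta$anglesDeg),
    metadata = as.list(meta$metadata))
}
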