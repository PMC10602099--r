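# ZStack construction, accessors and TIFF I/O.

#' Construct a ZStack
#'
#' @param voxels numeric array `[y, x, z, channel]` with intensities in
#'   `[0, 1]`, or a list of two `[y, x, z]` arrays named by channel.
#' @param pixelSize lateral calibration, um per pixel.
#' @param zStep axial calibration, um between slices.
#' @param channels channel names in array order; reordered to
#'   `c("nuclei", "actin")` if both are present.
#' @return A [ZStack-class] object.
#' @examples
#' v <- array(runif(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
#' zs <- ZStack(v, pixelSize = 1, zStep = 5)
#' nSlices(zs)
#' @export
ZStack <- function(voxels, pixelSize, zStep,
                   channels = c("nuclei", "actin")) {
  if (is.list(voxels)) {
    channels <- names(voxels)
    voxels <- array(unlist(voxels, use.names = FALSE),
                    dim = c(dim(voxels[[1]]), length(voxels)))
  }
  if (length(dim(voxels)) == 3) dim(voxels) <- c(dim(voxels), 1L)
  if (all(c("nuclei", "actin") %in% channels)) {
    ord <- match(c("nuclei", "actin"), channels)
    voxels <- voxels[, , , ord, drop = FALSE]
    channels <- c("nuclei", "actin")
  }
  new("ZStack", voxels = voxels, channels = channels,
      pixelSize = as.numeric(pixelSize), zStep = as.numeric(zStep))
}

#' @describeIn ZStack lateral calibration (um/px).
#' @param x a `ZStack`.
#' @export
setMethod("pixelSize", "ZStack", function(x) x@pixelSize)

#' @describeIn ZStack axial calibration (um).
#' @export
setMethod("zStep", "ZStack", function(x) x@zStep)

#' @describeIn ZStack number of z-slices.
#' @export
setMethod("nSlices", "ZStack", function(x) dim(x@voxels)[3])

#' @describeIn ZStack channel names, in array order.
#' @export
setMethod("channelNames", "ZStack", function(x) x@channels)

#' @describeIn ZStack one slice of one channel as a `[y, x]` matrix
#'   (`z` is 1-based).
#' @param z slice index, 1-based.
#' @param channel channel name or index.
#' @export
setMethod("getSlice", "ZStack", function(x, z, channel) {
  if (is.character(channel)) channel <- match(channel, x@channels)
  if (is.na(channel)) stop("unknown channel")
  if (z < 1 || z > nSlices(x)) stop("slice index out of range")
  x@voxels[, , z, channel]
})

setMethod("show", "ZStack", function(object) {
  d <- dim(object@voxels)
  cat("ZStack:", d[3], "slices of", d[1], "x", d[2], "px,",
      length(object@channels), "channels (",
      paste(object@channels, collapse = ", "), ")\n")
  cat("  calibration:", object@pixelSize, "um/px,", object@zStep,
      "um z-step\n")
})

#' Read a two-channel z-stack from TIFF
#'
#' Reads a multi-page grayscale TIFF holding both channels page-interleaved
#' (per slice: nuclei page, then actin page), or a pair of single-channel
#' multi-page files given as a length-2 path vector. Calibration is not
#' stored in the acquisition files and must be supplied.
#'
#' @param path path to the interleaved stack, or `c(nucleiPath, actinPath)`.
#' @param pixelSize lateral calibration, um per pixel.
#' @param zStep axial calibration, um.
#' @return A [ZStack-class].
#' @seealso [writeZStack()]
#' @export
readZStack <- function(path, pixelSize, zStep) {
  readPages <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(m) length(dim(m)) != 2, logical(1))))
      stop("expected grayscale pages")
    shapes <- vapply(pages, dim, integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      stop("non-uniform slice shapes")
    pages
  }
  if (length(path) == 2) {
    nuc <- readPages(path[1])
    act <- readPages(path[2])
    if (length(nuc) != length(act) || any(dim(nuc[[1]]) != dim(act[[1]])))
      stop("channel stacks must have identical shapes")
    nz <- length(nuc)
    vox <- array(0, dim = c(dim(nuc[[1]]), nz, 2L))
    for (z in seq_len(nz)) {
      vox[, , z, 1] <- nuc[[z]]
      vox[, , z, 2] <- act[[z]]
    }
  } else {
    pages <- readPages(path)
    if (length(pages) %% 2 != 0)
      stop("expected 2 channels (even page count), got ", length(pages),
           " pages")
    nz <- length(pages) / 2
    vox <- array(0, dim = c(dim(pages[[1]]), nz, 2L))
    for (z in seq_len(nz)) {
      vox[, , z, 1] <- pages[[2 * z - 1]]
      vox[, , z, 2] <- pages[[2 * z]]
    }
  }
  ZStack(vox, pixelSize = pixelSize, zStep = zStep)
}

#' Write a two-channel z-stack as multi-page TIFF
#'
#' Pages are 16-bit grayscale, interleaved per slice (nuclei, then actin),
#' the layout [readZStack()] expects. Intensities are clipped to `[0, 1]`.
#'
#' @param stack a [ZStack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeZStack <- function(stack, path) {
  stopifnot(is(stack, "ZStack"))
  nz <- nSlices(stack)
  pages <- vector("list", 2 * nz)
  for (z in seq_len(nz)) {
    pages[[2 * z - 1]] <- pmin(pmax(getSlice(stack, z, 1), 0), 1)
    pages[[2 * z]] <- pmin(pmax(getSlice(stack, z, 2), 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
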