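# Phase-I per-slice processing: binarization, iterative closing over an
# increasing disk schedule, void component extraction with background
# discarding, superimposition into final 2D candidates, patch preparation,
# representative-slice selection and nuclear counting.

#' Binarize one image slice
#'
#' Default is Otsu's threshold (256-level histogram) on the intensity range
#' of the slice; a fixed raw-intensity threshold is available. A constant
#' slice has no foreground/background split and falls back to an
#' all-background mask (with a message).
#'
#' @param slice numeric matrix, single-channel intensities.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold raw-intensity cutoff when `method = "fixed"`; pixels
#'   strictly above it are foreground.
#' @return logical matrix, `TRUE` = foreground (tissue).
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' table(binarizeSlice(img))
#' @export
binarizeSlice <- function(slice, method = c("otsu", "fixed"),
                          threshold = NA_real_) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.na(threshold)) stop("fixed binarization needs a threshold")
    return(slice > threshold)
  }
  rng <- range(slice)
  if (diff(rng) == 0) {
    message("binarizeSlice: constant slice, returning all-background mask")
    return(matrix(FALSE, nrow(slice), ncol(slice)))
  }
  norm <- (slice - rng[1]) / diff(rng)
  th <- EBImage::otsu(norm, range = c(0, 1), levels = 256L)
  norm > th
}

# Build a CandidateLumen2D from a single-component mask.
.candidate_from_mask <- function(mask, z, pixel_size, first_iter) {
  idx <- which(mask, arr.ind = TRUE)
  bbox <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
  new("CandidateLumen2D", z = as.integer(z), mask = mask,
      areaPx = nrow(idx), areaUm2 = nrow(idx) * pixel_size^2,
      bbox = as.integer(bbox),
      centroid = c(mean(idx[, 1]), mean(idx[, 2])),
      firstDetectIteration = as.integer(first_iter))
}

#' Extract void components at one closing radius
#'
#' Closes the foreground with a Euclidean disk of radius
#' `round(diskRadius / pixelSize)` px (floored at 1 px; round half up),
#' takes the complement (voids share the background's colour), labels
#' 4-connected components and discards the single largest one — the
#' background. Tie on area: the component containing the image corner is
#' discarded, else the lowest label.
#'
#' @param mask logical matrix, `TRUE` = tissue foreground.
#' @param diskRadius closing-disk radius, um.
#' @param pixelSize um per pixel.
#' @param minArea minimum component area, px^2 (components below it are
#'   dropped; default 0 keeps all).
#' @return list of logical matrices, one single-component void mask each
#'   (possibly empty).
#' @export
extractVoidComponents <- function(mask, diskRadius, pixelSize = 1,
                                  minArea = 0) {
  stopifnot(diskRadius > 0)
  r_px <- .um_to_px(diskRadius, pixelSize)
  closed <- binaryClose(mask, r_px, spacing = 1)
  voids <- !closed
  lab <- labelComponents(voids, connectivity = 4)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  sizes <- tabulate(lab, nbins = nlab)
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    corner <- lab[1, 1]
    biggest <- if (corner %in% biggest) corner else min(biggest)
  }
  keep <- setdiff(which(sizes >= max(1, minArea)), biggest)
  lapply(keep, function(l) lab == l)
}

#' Detect candidate 2D lumens on one slice
#'
#' Runs [extractVoidComponents()] at every radius of the closing schedule
#' and superimposes the per-iteration void masks by pixelwise union, so each
#' candidate is kept once, at its largest detected form (closing with a
#' larger disk never enlarges a void, so the union realizes the maximum over
#' iterations). The union is relabelled (4-connectivity) and each final
#' candidate records the 0-based index of the earliest iteration at which
#' any of its pixels was detected. Candidates below
#' `config@minCandidateArea` px^2 are dropped.
#'
#' @param mask logical matrix, `TRUE` = tissue foreground.
#' @param config an [AnalysisConfig-class] (closing schedule + area floor).
#' @param pixelSize um per pixel.
#' @param z slice index stamped on the candidates (1-based).
#' @return list of [CandidateLumen2D-class].
#' @export
detectCandidateLumens <- function(mask, config = AnalysisConfig(),
                                  pixelSize = 1, z = 1L) {
  radii <- diskRadii(config)
  un <- matrix(FALSE, nrow(mask), ncol(mask))
  first <- matrix(NA_integer_, nrow(mask), ncol(mask))
  for (i in seq_along(radii)) {
    comps <- extractVoidComponents(mask, radii[i], pixelSize)
    for (cm in comps) {
      newpix <- cm & is.na(first)
      first[newpix] <- i - 1L
      un <- un | cm
    }
  }
  lab <- labelComponents(un, connectivity = 4)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  out <- list()
  for (l in seq_len(nlab)) {
    cm <- lab == l
    if (sum(cm) < config@minCandidateArea) next
    out[[length(out) + 1]] <-
      .candidate_from_mask(cm, z, pixelSize, min(first[cm], na.rm = TRUE))
  }
  out
}

#' Prepare a classification patch for one candidate
#'
#' The candidate mask is dilated by `round(dilation / pixelSize)` px, its
#' tight bounding box is cropped from both channels at the candidate's
#' slice, padded symmetrically with zeros to a square, resized to
#' `patchSize` px (bilinear) and per-channel min-max normalized against
#' the full slice's dynamic range (not the crop's: a crop without nuclei
#' must stay dark rather than have its noise stretched to mid-gray). The
#' two channels are stacked (nuclei, actin) rather than blended,
#' preserving both stains for the classifier.
#'
#' @param candidate a [CandidateLumen2D-class].
#' @param stack the source [ZStack-class].
#' @param dilation dilation radius, um.
#' @param patchSize output side length, px.
#' @return A [CandidatePatch-class] with a
#'   `[patchSize, patchSize, 2]` array.
#' @export
preparePatch <- function(candidate, stack, dilation = 4, patchSize = 32L) {
  stopifnot(candidate@z >= 1, candidate@z <= nSlices(stack))
  ps <- pixelSize(stack)
  r_px <- .um_to_px(dilation, ps)
  dil <- binaryDilate(candidate@mask, r_px, spacing = 1)
  idx <- which(dil, arr.ind = TRUE)
  y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
  x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
  h <- y1 - y0 + 1; w <- x1 - x0 + 1
  side <- max(h, w)
  patch <- array(0, dim = c(patchSize, patchSize, 2L))
  for (ch in 1:2) {
    sl <- getSlice(stack, candidate@z, ch)
    rng <- range(sl)
    crop <- sl[y0:y1, x0:x1, drop = FALSE]
    crop <- if (diff(rng) > 0) (crop - rng[1]) / diff(rng) else crop * 0
    sq <- matrix(0, side, side)
    oy <- (side - h) %/% 2
    ox <- (side - w) %/% 2
    sq[oy + seq_len(h), ox + seq_len(w)] <- crop
    res <- EBImage::resize(sq, w = patchSize, h = patchSize)
    patch[, , ch] <- pmin(1, pmax(0, res))
  }
  new("CandidatePatch",
      id = sprintf("z%03d_y%d_x%d", candidate@z, y0, x0),
      patch = patch, z = candidate@z,
      bbox = as.integer(c(y0, x0, y1, x1)))
}

#' Select the representative slice of a stack
#'
#' The slice with the largest cellular region area: the binarized actin
#' foreground with its enclosed holes filled, so the measure is the area
#' inside the tissue outline (lumina and weakly stained cytoplasm count as
#' cellular region, as in high-content "cellular region" segmentation)
#' rather than the bright-structure area alone. Ties resolve to the lowest
#' slice index.
#'
#' @param stack a [ZStack-class].
#' @param config an [AnalysisConfig-class] (binarization settings).
#' @return 1-based slice index.
#' @export
selectRepresentativeSlice <- function(stack, config = AnalysisConfig()) {
  areas <- vapply(seq_len(nSlices(stack)), function(z) {
    m <- suppressMessages(binarizeSlice(getSlice(stack, z, "actin"),
                                        method = config@binarizeMethod,
                                        threshold = config@binarizeThreshold))
    sum(fillCavities(m))
  }, numeric(1))
  which.max(areas) # first maximum = lowest index on ties
}

#' Count nuclei in a stack
#'
#' Generic nuclear count: the nuclei channel is max-projected over z,
#' Gaussian-smoothed (mildly — heavy smoothing fuses near-neighbour nuclei
#' into blobs whose distance map has a single peak the watershed cannot
#' split), Otsu-thresholded, split by distance-transform watershed, and
#' the resulting segments are filtered by an area range and a minimum
#' nearest-neighbour centroid distance (segments closer than the minimum
#' are merged and counted once).
#'
#' @param stack a [ZStack-class] with a `nuclei` channel.
#' @param smoothSigma Gaussian sigma, um.
#' @param minArea,maxArea segment area bounds, um^2.
#' @param minDist minimum centroid separation, um.
#' @return integer count of surviving nuclei.
#' @export
countNuclei <- function(stack, smoothSigma = 1.5, minArea = 10,
                        maxArea = 500, minDist = 4) {
  ps <- pixelSize(stack)
  ich <- match("nuclei", channelNames(stack))
  proj <- apply(stack@voxels[, , , ich, drop = FALSE], c(1, 2), max)
  rng <- range(proj)
  if (diff(rng) == 0) return(0L)
  norm <- (proj - rng[1]) / diff(rng)
  sm <- EBImage::gblur(norm, sigma = max(0.5, smoothSigma / ps))
  th <- EBImage::otsu(sm, range = range(sm), levels = 256L)
  mask <- sm > th
  if (!any(mask)) return(0L)
  dm <- EBImage::distmap(EBImage::Image(mask))
  lab <- EBImage::imageData(EBImage::watershed(dm))
  nlab <- max(lab)
  if (nlab == 0) return(0L)
  cents <- NULL
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    area <- nrow(idx) * ps^2
    if (area < minArea || area > maxArea) next
    cents <- rbind(cents, c(mean(idx[, 1]), mean(idx[, 2])))
  }
  if (is.null(cents)) return(0L)
  n <- nrow(cents)
  if (n == 1) return(1L)
  # merge centroids closer than minDist (single-linkage clusters)
  d <- as.matrix(stats::dist(cents * ps))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (d[i, j] < minDist) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  length(unique(vapply(seq_len(n), find, integer(1))))
}
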