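# Grouping of true 2D lumens into 3D lumens, alpha-shape reconstruction and
# per-microtissue summaries.
#
# Reconstruction uses the grid alpha hull: the alpha hull of a point set is
# the complement of the union of all empty open alpha-balls, which equals
# the morphological closing of the set by a ball of radius alpha. The
# boundary point cloud of each lumen group is rasterized on its native
# (anisotropic) voxel grid, closed with a Euclidean ball of radius alpha in
# physical units (exact EDT), interior cavities are filled, and volume /
# surface area are integrated from the voxelization. The default alpha
# policy is the critical alpha: the smallest alpha (to 0.25 um) for which
# the closed set is a single connected region containing all points.

.bbox_overlap <- function(a, b) {
  # closed rectangles c(y0, x0, y1, x1); edge contact counts as overlap
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

#' Group true 2D lumens into 3D lumen groups
#'
#' Candidates are linked when their bounding boxes overlap in xy (closed
#' rectangles, edge contact counts) and their slice distance is at most
#' `gapTolerance + 1`. Groups are the connected components of this link
#' graph, split at any z-gap exceeding `gapTolerance` (default 0: any
#' missing slice splits the stack of 2D lumens, as a gap most probably
#' separates vertically stacked lumens).
#'
#' @param candidates list of [CandidateLumen2D-class] (the "true" ones).
#' @param gapTolerance tolerated number of consecutive missing slices.
#' @return list of [LumenGroup-class].
#' @export
groupLumens <- function(candidates, gapTolerance = 0L) {
  n <- length(candidates)
  if (n == 0) return(list())
  zs <- vapply(candidates, function(cd) cd@z, integer(1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (abs(zs[i] - zs[j]) > gapTolerance + 1L) next
    if (.bbox_overlap(candidates[[i]]@bbox, candidates[[j]]@bbox)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- list()
  for (r in unique(roots)) {
    idx <- which(roots == r)
    idx <- idx[order(zs[idx])]
    # split at z-gaps exceeding the tolerance
    segStart <- 1
    for (k in seq_along(idx)) {
      if (k == length(idx) ||
          zs[idx[k + 1]] - zs[idx[k]] > gapTolerance + 1L) {
        mem <- candidates[idx[segStart:k]]
        groups[[length(groups) + 1]] <- mem
        segStart <- k + 1
      }
    }
  }
  lapply(seq_along(groups), function(g)
    new("LumenGroup", members = groups[[g]], id = sprintf("g%03d", g)))
}

# 3D boundary voxels of a solid: voxels with a 6-neighbour outside the
# solid (array borders count as outside, so end-slice masks are caps and
# belong to the surface)
.solid_boundary3d <- function(occ) {
  d <- dim(occ)
  shift <- function(a, dy, dx, dz) {
    out <- array(FALSE, d)
    ys <- seq_len(d[1]) + dy; xs <- seq_len(d[2]) + dx
    zs <- seq_len(d[3]) + dz
    oky <- ys >= 1 & ys <= d[1]; okx <- xs >= 1 & xs <= d[2]
    okz <- zs >= 1 & zs <= d[3]
    out[which(oky), which(okx), which(okz)] <-
      a[ys[oky], xs[okx], zs[okz], drop = FALSE]
    out
  }
  inner <- shift(occ, 1, 0, 0) & shift(occ, -1, 0, 0) &
           shift(occ, 0, 1, 0) & shift(occ, 0, -1, 0) &
           shift(occ, 0, 0, 1) & shift(occ, 0, 0, -1)
  occ & !inner
}

# boundary pixels of a 2D mask: mask pixels with a 4-neighbour outside
.mask_boundary <- function(v) {
  inner <- rbind(FALSE, v[-nrow(v), , drop = FALSE]) &
           rbind(v[-1, , drop = FALSE], FALSE) &
           cbind(FALSE, v[, -ncol(v), drop = FALSE]) &
           cbind(v[, -1, drop = FALSE], FALSE)
  v & !inner
}

# smallest alpha (to `tol` um) whose ball-closing of `occ` is one
# 6-connected component; search by doubling then bisection
.critical_alpha <- function(occ, spacing, tol = 0.25) {
  connected <- function(a) {
    cl <- binaryClose(occ, a, spacing)
    max(labelComponents(cl)) == 1L
  }
  lo <- 0
  hi <- max(spacing)
  cap <- 64 * max(spacing)
  while (!connected(hi)) {
    lo <- hi
    hi <- hi * 2
    if (hi > cap) stop("no connecting alpha below ", cap, " um")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (connected(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Reconstruct one 3D lumen from a group
#'
#' The member masks are stacked into a 3D solid and its boundary voxels
#' form the point cloud, at physical coordinates `(x px * pixelSize, y px *
#' pixelSize, z slice * zStep)` (0-based indices). In-plane mask rims
#' contribute the lateral surface; the first and last slice masks are the
#' end caps — without them the surface would be an open tube and no alpha
#' could enclose it. The cloud is reconstructed as a grid alpha hull (see
#' the package vignette): ball-closing at alpha, cavity filling, voxel
#' integration of volume (um^3) and exposed-face surface area (um^2). With
#' `alphaPolicy = "auto"` the critical alpha is used and recorded in the
#' result. A group spanning a single slice has a coplanar cloud; its
#' volume is the stated extrusion convention `mask area x zStep` (surface:
#' two faces plus the rim).
#'
#' @param group a [LumenGroup-class].
#' @param pixelSize um per pixel.
#' @param zStep um between slices.
#' @param alphaPolicy `"auto"` (critical alpha) or `"fixed"`.
#' @param alpha fixed alpha, um (when `alphaPolicy = "fixed"`).
#' @return A [Lumen3D-class].
#' @export
reconstructLumen <- function(group, pixelSize, zStep,
                             alphaPolicy = c("auto", "fixed"),
                             alpha = NA_real_) {
  alphaPolicy <- match.arg(alphaPolicy)
  stopifnot(is(group, "LumenGroup"), length(group@members) > 0)
  mem <- group@members
  zs <- vapply(mem, function(m) m@z, integer(1))
  zmin <- min(zs); zmax <- max(zs)

  if (zmin == zmax) {
    # coplanar cloud: extrusion convention
    un <- mem[[1]]@mask
    if (length(mem) > 1) for (m in mem[-1]) un <- un | m@mask
    b <- which(.mask_boundary(un), arr.ind = TRUE)
    pts <- cbind(x = (b[, 2] - 1) * pixelSize, y = (b[, 1] - 1) * pixelSize,
                 z = rep((zmin - 1) * zStep, nrow(b)))
    areaPx <- sum(un)
    perimPx <- sum(.mask_boundary(un)) # rim pixel count
    vol <- areaPx * pixelSize^2 * zStep
    surf <- 2 * areaPx * pixelSize^2 + perimPx * pixelSize * zStep
    return(new("Lumen3D", groupId = group@id, points = pts,
               alpha = NA_real_, volume = vol, surfaceArea = surf,
               sliceSpan = c(zmin, zmax)))
  }

  bb <- do.call(rbind, lapply(mem, function(m) m@bbox))
  y0 <- min(bb[, 1]); x0 <- min(bb[, 2])
  ny <- max(bb[, 3]) - y0 + 1L
  nx <- max(bb[, 4]) - x0 + 1L
  nz <- zmax - zmin + 1L
  solid <- array(FALSE, dim = c(ny, nx, nz))
  for (m in mem) {
    solid[, , m@z - zmin + 1L] <- solid[, , m@z - zmin + 1L] |
      m@mask[y0:(y0 + ny - 1L), x0:(x0 + nx - 1L)]
  }
  occ <- .solid_boundary3d(solid)
  bidx <- which(occ, arr.ind = TRUE)
  pts <- cbind(x = (bidx[, 2] + x0 - 2) * pixelSize,
               y = (bidx[, 1] + y0 - 2) * pixelSize,
               z = (bidx[, 3] + zmin - 2) * zStep)
  spacing <- c(pixelSize, pixelSize, zStep)
  aUsed <- if (alphaPolicy == "fixed") {
    if (is.na(alpha) || alpha <= 0) stop("fixed alpha must be > 0")
    alpha
  } else .critical_alpha(occ, spacing)
  hull <- fillCavities(binaryClose(occ, aUsed, spacing))
  vol <- sum(hull) * pixelSize^2 * zStep
  surf <- voxelSurfaceArea(hull, spacing)
  new("Lumen3D", groupId = group@id, points = pts, alpha = aUsed,
      volume = vol, surfaceArea = surf, sliceSpan = c(zmin, zmax))
}

#' @describeIn reconstructLumen lumen volume, um^3.
#' @param x a `Lumen3D`.
#' @export
setMethod("lumenVolume", "Lumen3D", function(x) x@volume)

#' @describeIn reconstructLumen lumen surface area, um^2.
#' @export
setMethod("surfaceArea", "Lumen3D", function(x) x@surfaceArea)

setMethod("show", "Lumen3D", function(object) {
  cat("Lumen3D", object@groupId, ": volume", signif(object@volume, 6),
      "um^3, surface", signif(object@surfaceArea, 6), "um^2, slices",
      object@sliceSpan[1], "-", object@sliceSpan[2],
      if (!is.na(object@alpha)) paste0("(alpha ", object@alpha, " um)")
      else "(extruded)", "\n")
})

#' Summarize a microtissue's lumens
#'
#' @param lumens list of [Lumen3D-class] (possibly empty: microtissues
#'   without detected lumens are reported with count 0 and volume 0).
#' @param id microtissue identifier.
#' @return A [MicrotissueResult-class].
#' @export
summarizeMicrotissue <- function(lumens, id = "microtissue") {
  MicrotissueResult(id,
    volumes = vapply(lumens, lumenVolume, numeric(1)),
    surfaceAreas = vapply(lumens, surfaceArea, numeric(1)))
}

#' Run the full lumen pipeline on a stack
#'
#' Binarizes each slice, detects candidate voids across the closing
#' schedule, prepares classification patches, filters candidates through
#' the classifier, groups survivors across slices and reconstructs each
#' group as a 3D lumen.
#'
#' @param stack a [ZStack-class].
#' @param classifier a [LumenClassifier-class] (trained, or an oracle).
#' @param config an [AnalysisConfig-class].
#' @param id microtissue identifier for the summary.
#' @return list with `result` ([MicrotissueResult-class]), `lumens`,
#'   `groups`, `candidates` and the per-candidate `classification`
#'   data.frame.
#' @export
analyzeLumens <- function(stack, classifier, config = AnalysisConfig(),
                          id = "microtissue") {
  ps <- pixelSize(stack)
  candidates <- list()
  for (z in seq_len(nSlices(stack))) {
    m <- suppressMessages(binarizeSlice(getSlice(stack, z, "actin"),
                                        method = config@binarizeMethod,
                                        threshold = config@binarizeThreshold))
    candidates <- c(candidates,
                    detectCandidateLumens(m, config, pixelSize = ps, z = z))
  }
  if (length(candidates) == 0) {
    return(list(result = MicrotissueResult(id), lumens = list(),
                groups = list(), candidates = list(),
                classification = data.frame(probability = numeric(0),
                                            label = logical(0))))
  }
  patches <- if (classifier@kind == "oracle") list()
             else lapply(candidates, preparePatch, stack = stack,
                         dilation = config@patchDilation,
                         patchSize = config@patchSize)
  cls <- classifyCandidates(classifier, patches, candidates = candidates)
  keep <- candidates[cls$label]
  groups <- groupLumens(keep, gapTolerance = config@gapTolerance)
  lumens <- lapply(groups, reconstructLumen, pixelSize = ps,
                   zStep = zStep(stack), alphaPolicy = config@alphaPolicy,
                   alpha = config@alphaFixed)
  list(result = summarizeMicrotissue(lumens, id), lumens = lumens,
       groups = groups, candidates = candidates, classification = cls)
}
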