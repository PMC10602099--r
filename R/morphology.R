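# Binary morphology with Euclidean ball/disk structuring elements, built on
# the exact anisotropic squared EDT in src/morphology.cpp. The structuring
# element is pinned to {d : |d|^2 <= r^2} in physical units; dilation and
# erosion are the distance-threshold characterizations
#   dilate(A) = { x : dist(x, A)  <= r }
#   erode(A)  = { x : dist(x, A^c) > r }
# and closing pads the array with background so behaviour at the image
# border matches the usual pad-with-zeros convention.

.sq_tol <- function(radius) radius^2 * (1 + 1e-9) + 1e-9

#' Squared Euclidean distance transform
#'
#' Exact squared distance from every element of a 2D or 3D logical array to
#' the nearest `TRUE` element, in physical units given per-axis spacings.
#'
#' @param mask logical matrix or 3D array.
#' @param spacing numeric vector of per-dimension physical step sizes
#'   (recycled to the number of dimensions).
#' @return numeric array of `dim(mask)` with squared distances (`Inf` if
#'   `mask` has no `TRUE` element).
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' sqDistanceTransform(m)[3, 5]  # 4
#' @export
sqDistanceTransform <- function(mask, spacing = 1) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or 3D array")
  spacing <- rep_len(as.numeric(spacing), length(d))
  out <- cpp_sqedt(as.logical(mask), as.integer(d), spacing)
  array(out, dim = d)
}

#' @rdname binaryClose
#' @export
binaryDilate <- function(mask, radius, spacing = 1) {
  if (radius <= 0) return(mask & TRUE)
  sq <- sqDistanceTransform(mask, spacing)
  out <- sq <= .sq_tol(radius)
  dim(out) <- dim(mask)
  out
}

#' @rdname binaryClose
#' @export
binaryErode <- function(mask, radius, spacing = 1) {
  if (radius <= 0) return(mask & TRUE)
  d <- dim(mask)
  spacing <- rep_len(as.numeric(spacing), length(d))
  # outside the array counts as background: pad before the EDT so border
  # pixels are eroded exactly as the offset definition prescribes
  pad <- ceiling(radius / spacing) + 1
  big <- array(FALSE, dim = d + 2 * pad)
  idx <- lapply(seq_along(d), function(i) seq_len(d[i]) + pad[i])
  if (length(d) == 2) {
    big[idx[[1]], idx[[2]]] <- mask
    sq <- sqDistanceTransform(!big, spacing)
    out <- (sq > .sq_tol(radius))[idx[[1]], idx[[2]]]
  } else {
    big[idx[[1]], idx[[2]], idx[[3]]] <- mask
    sq <- sqDistanceTransform(!big, spacing)
    out <- (sq > .sq_tol(radius))[idx[[1]], idx[[2]], idx[[3]]]
  }
  dim(out) <- d
  out
}

#' Binary morphological operators with a Euclidean ball
#'
#' Dilation, erosion and closing of a 2D or 3D logical array by the
#' Euclidean ball of physical radius `radius` (a disk when the array is
#' 2D). Closing pads with background (`FALSE`) before dilating so the
#' result matches the conventional zero-padded closing, then crops back.
#'
#' @param mask logical matrix or 3D array; `TRUE` is foreground.
#' @param radius structuring-element radius in physical units.
#' @param spacing per-dimension physical step sizes.
#' @return logical array of the same shape.
#' @examples
#' wall <- matrix(FALSE, 15, 15)
#' wall[5:11, 5] <- wall[5:11, 11] <- wall[5, 5:11] <- TRUE
#' wall[11, 5:8] <- TRUE  # ring with a gap
#' sum(binaryClose(wall, 3) & !wall) > 0  # gap healed
#' @export
binaryClose <- function(mask, radius, spacing = 1) {
  if (radius <= 0) return(mask & TRUE)
  d <- dim(mask)
  spacing <- rep_len(as.numeric(spacing), length(d))
  pad <- ceiling(radius / spacing) + 1
  dpad <- d + 2 * pad
  big <- array(FALSE, dim = dpad)
  idx <- lapply(seq_along(d), function(i) seq_len(d[i]) + pad[i])
  if (length(d) == 2) {
    big[idx[[1]], idx[[2]]] <- mask
    closed <- binaryErode(binaryDilate(big, radius, spacing), radius, spacing)
    closed[idx[[1]], idx[[2]]]
  } else {
    big[idx[[1]], idx[[2]], idx[[3]]] <- mask
    closed <- binaryErode(binaryDilate(big, radius, spacing), radius, spacing)
    closed[idx[[1]], idx[[2]], idx[[3]]]
  }
}

#' Label connected components
#'
#' Components of a logical array: 4- or 8-connectivity in 2D, face (6-)
#' connectivity in 3D. Labels start at 1 in column-major scan order of each
#' component's first pixel; background is 0.
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 4 or 8 (2D only; 3D always uses 6).
#' @return integer array of labels, same shape as `mask`.
#' @export
labelComponents <- function(mask, connectivity = 4) {
  d <- dim(mask)
  if (length(d) == 2) {
    lab <- cpp_label2d(as.logical(mask), as.integer(d), as.integer(connectivity))
  } else {
    lab <- cpp_label3d(as.logical(mask), as.integer(d))
  }
  array(lab, dim = d)
}

# Fill cavities: TRUE voxels plus any background region not connected to the
# array border (face connectivity). Works for 2D and 3D.
fillCavities <- function(mask) {
  d <- dim(mask)
  lab <- labelComponents(!mask, connectivity = 4)
  if (length(d) == 2) {
    border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
  } else {
    border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                       lab[, , 1], lab[, , d[3]]))
  }
  border <- setdiff(border, 0L)
  out <- mask | (lab != 0 & !(lab %in% border))
  dim(out) <- d
  out
}

# Total exposed-face area of a voxel mask, physical units.
voxelSurfaceArea <- function(mask, spacing = 1) {
  d <- dim(mask)
  spacing <- rep_len(as.numeric(spacing), length(d))
  cpp_voxel_surface(as.logical(mask), as.integer(d), spacing)
}

# round-half-up conversion of a physical length to pixels, floored at 1 px
.um_to_px <- function(length_um, pixel_size) {
  max(1L, as.integer(floor(length_um / pixel_size + 0.5)))
}
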