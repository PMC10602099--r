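# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's EDT machinery: dilation is explicit offset shifting
# with the structuring element {(dy,dx): dy^2+dx^2 <= r^2}, erosion is the
# complement-dilation dual, and labeling is flood fill.

# shift a matrix by (dy, dx), padding with `fill`
shift_mat <- function(m, dy, dx, fill = FALSE) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[which(oky), which(okx)] <- m[ys[oky], xs[okx], drop = FALSE]
  out
}

disk_offsets <- function(r) {
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off[off$dy^2 + off$dx^2 <= r^2, ]
}

# brute-force closing on an infinite background: pad by r, dilate by
# explicit offsets, erode as the dual, crop
brute_close <- function(mask, r) {
  off <- disk_offsets(r)
  ny0 <- nrow(mask); nx0 <- ncol(mask)
  pm <- matrix(FALSE, ny0 + 2 * r, nx0 + 2 * r)
  pm[r + seq_len(ny0), r + seq_len(nx0)] <- mask
  dil <- Reduce(`|`, lapply(seq_len(nrow(off)), function(k)
    shift_mat(pm, off$dy[k], off$dx[k])))
  ero <- !Reduce(`|`, lapply(seq_len(nrow(off)), function(k)
    shift_mat(!dil, off$dy[k], off$dx[k], fill = TRUE)))
  ero[r + seq_len(ny0), r + seq_len(nx0)]
}

# flood-fill labeling (4-connectivity), queue-based
flood_label <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      y <- (p - 1L) %% ny + 1L; x <- (p - 1L) %/% ny + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        yy <- y + d[1]; xx <- x + d[2]
        if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
        q <- (xx - 1L) * ny + yy
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# brute-force void extraction: close, complement, flood-fill label, discard
# the single largest component (tie: corner component, else lowest label)
brute_voids <- function(mask, r) {
  voids <- !brute_close(mask, r)
  lab <- flood_label(voids)
  if (max(lab) == 0L) return(list())
  sizes <- tabulate(lab, nbins = max(lab))
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    corner <- lab[1, 1]
    biggest <- if (corner %in% biggest) corner else min(biggest)
  }
  lapply(setdiff(seq_len(max(lab)), biggest), function(l) lab == l)
}

# square-annulus wall with an optional gap through the top wall
make_ring <- function(n = 48, inner0 = 12, t = 5, gap = 0) {
  m <- matrix(FALSE, n, n)
  m[inner0:(n - inner0), inner0:(n - inner0)] <- TRUE
  m[(inner0 + t):(n - inner0 - t), (inner0 + t):(n - inner0 - t)] <- FALSE
  if (gap > 0) {
    gc0 <- round(n / 2) - (gap - 1) %/% 2
    m[inner0:(inner0 + t - 1), gc0:(gc0 + gap - 1)] <- FALSE
  }
  m
}

# large-annulus wall (circular), hole radius rh, wall thickness t, gap width
# w px realized as a sector through the wall; hole radius > the largest
# closing disk so the void is never filled outright
make_big_ring <- function(n = 128, rh = 45, t = 10, gap = 0) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  m <- d >= rh & d <= rh + t
  if (gap > 0) {
    ang <- atan2(outer(seq_len(n) - ctr, rep(1, n)),
                 outer(rep(1, n), seq_len(n) - ctr))
    theta <- asin(min(1, gap / (2 * rh)))
    m[m & abs(ang - pi / 2) < theta] <- FALSE
  }
  m
}

# candidate object from a full-slice mask (test fixtures)
make_candidate <- function(mask, z, pixel_size = 1, iter = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  methods::new("CandidateLumen2D", z = as.integer(z), mask = mask,
               areaPx = nrow(idx), areaUm2 = nrow(idx) * pixel_size^2,
               bbox = as.integer(c(min(idx[, 1]), min(idx[, 2]),
                                   max(idx[, 1]), max(idx[, 2]))),
               centroid = c(mean(idx[, 1]), mean(idx[, 2])),
               firstDetectIteration = as.integer(iter))
}

# per-slice disk masks of a voxelized sphere of radius r um, centered,
# sliced every zstep um; returns a list of CandidateLumen2D
sphere_candidates <- function(r, ps = 1, zstep = 5, n = NULL) {
  if (is.null(n)) n <- ceiling(2 * r / ps) + 9
  ctr <- (n + 1) / 2
  zs <- seq(-r, r, by = zstep)
  cands <- list()
  for (i in seq_along(zs)) {
    rz2 <- r^2 - zs[i]^2
    if (rz2 <= 0) next
    m <- matrix(FALSE, n, n)
    for (y in seq_len(n)) {
      dx2 <- rz2 / ps^2 - (y - ctr)^2
      if (dx2 < 0) next
      xr <- sqrt(dx2)
      xs <- max(1, ceiling(ctr - xr)):min(n, floor(ctr + xr))
      m[y, xs] <- TRUE
    }
    if (any(m)) cands[[length(cands) + 1]] <- make_candidate(m, i, ps)
  }
  cands
}

# ellipsoid stack spec with k sealed lumens at deterministic positions;
# in-plane semi-axes >= 10 um so off-equator slices stay comfortably above
# the 6 um initial closing disk, and analytic bounding boxes are pairwise
# xy-disjoint wherever slice ranges overlap (groups cannot merge)
k_lumen_spec <- function(k, seed, noise = 0) {
  pos <- list(c(-14, -11, 0), c(15, 12, 0), c(-8, 15, -10), c(8, -16, 10))
  ax <- list(c(11, 10, 10), c(11, 10, 9), c(10, 11, 9), c(10, 10, 9))
  StackSpec(dim = c(21L, 192L, 192L), tissueRadius = 45, nNuclei = 25L,
            seed = as.integer(seed), noiseSd = noise,
            lumens = lapply(seq_len(k), function(i)
              list(center = pos[[i]], semiAxes = ax[[i]], gapWidth = 0)))
}

# NIPALS PLS1 oracle: first-component scores against a centered dummy
pls1_scores <- function(X, y01) {
  Xc <- scale(X, scale = FALSE)
  yc <- y01 - mean(y01)
  w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
  drop(Xc %*% w)
}

# trapezoidal ROC-curve AUC oracle (explicit curve integration)
trapezoid_auc <- function(scores, positive) {
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(ths, function(t) mean(scores[positive] >= t),
                     numeric(1)), 1)
  fpr <- c(0, vapply(ths, function(t) mean(scores[!positive] >= t),
                     numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
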