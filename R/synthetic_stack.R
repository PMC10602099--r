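# Seeded generator for microtissue z-stacks with known lumens.
#
# Emulated geometry: a spherical microtissue with a bright cortical actin
# shell and dim cytoplasm, containing ellipsoidal luminal voids whose bright
# actin walls may carry an angular gap of controlled chord width (the
# feature the closing schedule must heal: a gapped lumen leaks into the
# surrounding void and is only separated once the closing disk spans the
# gap). Nuclei are isotropic Gaussian blobs placed by rejection sampling
# with a minimum xy separation, so the max-projection nuclear count is
# exact by construction.

#' Construct a StackSpec
#'
#' Defaults describe a realistic single microtissue acquired at 20x: a
#' 55 um-radius tissue in a 256 x 256 px field at 1 um/px, 25 slices at the
#' 5 um z-step, 40 nuclei of 4 um radius, 4 um actin walls and 2% additive
#' noise. The default gapped lumen uses a 6 um gap: a gap is healable only
#' if the disk that seals it (radius ~ w^2/(4t) + t/4 for chord w through
#' wall thickness t) is smaller than the lumen's own in-plane radius,
#' which would fill the void outright. (The nucleus count is bounded by the non-overlap constraint:
#' sequential placement with the default 2.2-radius xy separation jams
#' around ~50 nuclei at this tissue size.)
#'
#' @param dim integer `c(z, y, x)`.
#' @param pixelSize um per pixel.
#' @param zStep um between slices.
#' @param tissueRadius um.
#' @param nNuclei number of nuclei.
#' @param nucleusRadius um.
#' @param lumens list of `list(center = c(x, y, z), semiAxes = c(a, b, c),
#'   gapWidth = g)`, all um; `center` is relative to the tissue center.
#' @param wallThickness um.
#' @param noiseSd additive Gaussian noise sd (fraction of dynamic range).
#' @param seed integer; fixes all randomness of the generator.
#' @return A [StackSpec-class].
#' @export
StackSpec <- function(dim = c(25L, 256L, 256L), pixelSize = 1, zStep = 5,
                      tissueRadius = 55, nNuclei = 40L, nucleusRadius = 4,
                      lumens = list(
                        list(center = c(-18, -15, 0), semiAxes = c(14, 12, 12),
                             gapWidth = 0),
                        list(center = c(20, 18, 5), semiAxes = c(10, 11, 9),
                             gapWidth = 6)),
                      wallThickness = 4, noiseSd = 0.02, seed = 1L) {
  new("StackSpec", dim = as.integer(dim), pixelSize = as.numeric(pixelSize),
      zStep = as.numeric(zStep), tissueRadius = as.numeric(tissueRadius),
      nNuclei = as.integer(nNuclei), nucleusRadius = as.numeric(nucleusRadius),
      lumens = lumens, wallThickness = as.numeric(wallThickness),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# intensity levels of the noiseless phantom
.SIM_LEVELS <- list(exterior = 0.05, cytoplasm = 0.15, wall = 0.9,
                    void = 0.05, nucleiBg = 0.03, nucleusAmp = 0.9)

#' Generate a synthetic microtissue stack with ground truth
#'
#' Builds the two-channel phantom described by a [StackSpec()] and the
#' matching [GroundTruth-class]: per-lumen interior voxel labels (assigned
#' before noise, so the truth is independent of the noise level), analytic
#' ellipsoid volumes `4/3 pi a b c`, and nucleus centers.
#'
#' @param spec a [StackSpec-class].
#' @return `list(stack = ZStack, truth = GroundTruth)`.
#' @examples
#' sim <- generateMicrotissueStack(StackSpec(seed = 7L))
#' sim$truth@volumes
#' @export
generateMicrotissueStack <- function(spec) {
  stopifnot(is(spec, "StackSpec"))
  validObject(spec)
  set.seed(spec@seed)
  nz <- spec@dim[1]; ny <- spec@dim[2]; nx <- spec@dim[3]
  ps <- spec@pixelSize; zs <- spec@zStep
  lv <- .SIM_LEVELS

  # physical coordinates of voxel centers (0-based index * calibration)
  xs <- (seq_len(nx) - 1) * ps
  ys <- (seq_len(ny) - 1) * ps
  zz <- (seq_len(nz) - 1) * zs
  cx <- mean(range(xs)); cy <- mean(range(ys)); cz <- mean(range(zz))

  DX <- array(rep(xs, each = ny), dim = c(ny, nx, nz)) - cx
  DY <- array(rep(ys, times = nx * nz), dim = c(ny, nx, nz)) - cy
  DZ <- array(rep(zz, each = ny * nx), dim = c(ny, nx, nz)) - cz
  RT <- sqrt(DX^2 + DY^2 + DZ^2)

  actin <- array(lv$exterior, dim = c(ny, nx, nz))
  inside <- RT <= spec@tissueRadius
  actin[inside] <- lv$cytoplasm
  shell <- abs(RT - spec@tissueRadius) <= spec@wallThickness / 2
  actin[shell] <- lv$wall

  labels <- array(0L, dim = c(ny, nx, nz))
  volumes <- numeric(length(spec@lumens))
  gapAngles <- runif(max(1, length(spec@lumens)), 0, 2 * pi)
  for (k in seq_along(spec@lumens)) {
    lu <- spec@lumens[[k]]
    ctr <- c(cx, cy, cz) + lu$center
    a <- lu$semiAxes
    q <- sqrt(((DX + cx - ctr[1]) / a[1])^2 +
              ((DY + cy - ctr[2]) / a[2])^2 +
              ((DZ + cz - ctr[3]) / a[3])^2)
    interior <- q < 1
    wallBand <- q >= 1 & q <= 1 + spec@wallThickness / mean(a)
    if (lu$gapWidth > 0) {
      axy <- mean(a[1:2])
      theta <- asin(min(1, lu$gapWidth / (2 * axy)))
      ang <- atan2(DY + cy - ctr[2], DX + cx - ctr[1])
      dphi <- abs(((ang - gapAngles[k] + pi) %% (2 * pi)) - pi)
      wallBand <- wallBand & dphi > theta
    }
    actin[wallBand] <- lv$wall
    actin[interior] <- lv$void
    newlab <- interior & labels == 0L
    labels[newlab] <- k
    volumes[k] <- 4 / 3 * pi * prod(a)
  }

  # nuclei: rejection sampling; xy separation makes projection counts exact
  nuc <- array(lv$nucleiBg, dim = c(ny, nx, nz))
  centers <- matrix(numeric(0), ncol = 3,
                    dimnames = list(NULL, c("x", "y", "z")))
  minSepXy <- 2.2 * spec@nucleusRadius + 1
  maxReach <- spec@tissueRadius - spec@wallThickness - spec@nucleusRadius
  tries <- 0
  while (nrow(centers) < spec@nNuclei && tries < 20000 * max(1, spec@nNuclei)) {
    tries <- tries + 1
    cand <- c(runif(1, cx - maxReach, cx + maxReach),
              runif(1, cy - maxReach, cy + maxReach),
              runif(1, cz - maxReach, cz + maxReach))
    if (sqrt(sum((cand - c(cx, cy, cz))^2)) > maxReach) next
    inLumen <- FALSE
    for (lu in spec@lumens) {
      ctr <- c(cx, cy, cz) + lu$center
      pad <- lu$semiAxes + spec@wallThickness + spec@nucleusRadius
      if (sqrt(sum(((cand - ctr) / pad)^2)) < 1) { inLumen <- TRUE; break }
    }
    if (inLumen) next
    if (nrow(centers) > 0 &&
        min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) <
          minSepXy) next
    centers <- rbind(centers, cand)
  }
  if (nrow(centers) < spec@nNuclei)
    stop("could not place ", spec@nNuclei, " nuclei; tissue too crowded")
  reach <- 3 * spec@nucleusRadius
  for (i in seq_len(nrow(centers))) {
    ix <- which(abs(xs - centers[i, 1]) <= reach)
    iy <- which(abs(ys - centers[i, 2]) <= reach)
    iz <- which(abs(zz - centers[i, 3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((ys[iy] - centers[i, 2])^2,
                      (xs[ix] - centers[i, 1])^2, "+"),
                (zz[iz] - centers[i, 3])^2, "+")
    nuc[iy, ix, iz] <- pmin(1, nuc[iy, ix, iz] +
      lv$nucleusAmp * exp(-d2 / (0.5 * spec@nucleusRadius^2)))
  }

  if (spec@noiseSd > 0) {
    n <- length(actin)
    actin <- pmin(1, pmax(0, actin + rnorm(n, 0, spec@noiseSd)))
    nuc <- pmin(1, pmax(0, nuc + rnorm(n, 0, spec@noiseSd)))
  }

  vox <- array(0, dim = c(ny, nx, nz, 2L))
  vox[, , , 1] <- nuc
  vox[, , , 2] <- actin
  stack <- ZStack(vox, pixelSize = ps, zStep = zs,
                  channels = c("nuclei", "actin"))
  truth <- new("GroundTruth", labels = labels, volumes = volumes,
               nucleiCenters = centers)
  list(stack = stack, truth = truth)
}

#' Generate labeled training patches
#'
#' Desk-scale counterpart of a manually marked lumen training set. "True"
#' patches show an enclosed dark void ringed by bright actin inside
#' cytoplasm, with nuclei outside the void. "False" patches cycle through
#' the three failure modes the pipeline encounters: background notches
#' cutting in from the patch border, rimless dark noise blobs, and the
#' hard negative — a ringed dark region that is actually a tissue
#' cross-section, betrayed by the nuclei lying inside it. All carry a
#' plausible nuclei channel and additive noise.
#'
#' @param nTrue,nFalse patch counts (>= 0).
#' @param seed integer seed; the full set is reproducible from it.
#' @param patchSize side length, px.
#' @return `list(patches = list of CandidatePatch, labels = logical)`.
#' @export
generateCandidatePatches <- function(nTrue, nFalse, seed = 1L,
                                     patchSize = 32L) {
  stopifnot(nTrue >= 0, nFalse >= 0)
  set.seed(as.integer(seed))
  n <- nTrue + nFalse
  labels <- rep(c(TRUE, FALSE), c(nTrue, nFalse))
  gx <- matrix(rep(seq_len(patchSize), each = patchSize), patchSize)
  gy <- matrix(rep(seq_len(patchSize), times = patchSize), patchSize)
  mk <- function(truth) {
    cyt <- runif(1, 0.3, 0.5)
    actin <- matrix(cyt, patchSize, patchSize) +
      matrix(rnorm(patchSize^2, 0, 0.04), patchSize)
    ctr <- patchSize / 2 + runif(2, -2, 2)
    voidMask <- NULL     # region nuclei must avoid (true) or crowd (false)
    nucleiInside <- FALSE
    if (truth) {
      # void spans ~50-95% of the patch, matching the tight-cropped
      # geometry preparePatch() produces around a dilated candidate (the
      # void often runs close to, sometimes onto, the crop border)
      ax <- runif(2, patchSize / 4.2, patchSize / 2.1)
      phi <- runif(1, 0, pi)
      dx <- (gx - ctr[1]) * cos(phi) + (gy - ctr[2]) * sin(phi)
      dy <- -(gx - ctr[1]) * sin(phi) + (gy - ctr[2]) * cos(phi)
      q <- sqrt((dx / ax[1])^2 + (dy / ax[2])^2)
      actin[q < 1] <- 0.05
      ring <- q >= 1 & q < 1 + runif(1, 0.2, 0.35)
      actin[ring] <- runif(1, 0.75, 1)
      voidMask <- q < 1
    } else {
      mode <- sample(3, 1)
      if (mode == 1) {
        # border notch: background wedge cutting in from an edge
        ang <- runif(1, 0, 2 * pi)
        nx_ <- cos(ang); ny_ <- sin(ang)
        depth <- runif(1, 0.55, 0.85) * patchSize / 2
        proj <- (gx - patchSize / 2) * nx_ + (gy - patchSize / 2) * ny_
        actin[proj > patchSize / 2 - depth] <- 0.05
      } else if (mode == 2) {
        # rimless noise void
        ax <- runif(2, patchSize / 8, patchSize / 4)
        q <- sqrt(((gx - ctr[1]) / ax[1])^2 + ((gy - ctr[2]) / ax[2])^2)
        actin[q < 1] <- runif(1, 0.05, 0.12)
      } else {
        # hard negative: ringed dark tissue cross-section, nuclei inside
        ax <- runif(2, patchSize / 4.5, patchSize / 2.6)
        q <- sqrt(((gx - ctr[1]) / ax[1])^2 + ((gy - ctr[2]) / ax[2])^2)
        actin[q < 1] <- runif(1, 0.05, 0.15)
        actin[q >= 1 & q < 1 + runif(1, 0.2, 0.35)] <- runif(1, 0.75, 1)
        voidMask <- q < 1
        nucleiInside <- TRUE
      }
    }
    nucch <- matrix(0.03, patchSize, patchSize)
    for (b in seq_len(sample(0:4, 1) + as.integer(nucleiInside) * 2)) {
      for (try in 1:30) {
        bc <- runif(2, 3, patchSize - 3)
        inVoid <- !is.null(voidMask) &&
          voidMask[pmin(patchSize, pmax(1, round(bc[2]))),
                   pmin(patchSize, pmax(1, round(bc[1])))]
        if (nucleiInside == inVoid) break
      }
      d2 <- (gx - bc[1])^2 + (gy - bc[2])^2
      nucch <- nucch + 0.6 * exp(-d2 / runif(1, 4, 9))
    }
    patch <- array(0, dim = c(patchSize, patchSize, 2L))
    # keep the absolute [0,1] scale: pipeline patches are normalized
    # against the slice dynamic range, so sparse channels stay dark
    noise <- function(m) pmin(1, pmax(0, m + rnorm(length(m), 0, 0.03)))
    patch[, , 1] <- noise(nucch)
    patch[, , 2] <- noise(actin)
    patch
  }
  patches <- vector("list", n)
  for (i in seq_len(n))
    patches[[i]] <- new("CandidatePatch", id = sprintf("sim%05d", i),
                        patch = mk(labels[i]), z = 1L,
                        bbox = c(1L, 1L, patchSize, patchSize))
  list(patches = patches, labels = labels)
}
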