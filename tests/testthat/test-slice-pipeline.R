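# Per-slice processing: binarization, void extraction, schedule detection,
# patch preparation, representative slice, nuclei counting.

test_that("binarization falls back on constant slices and separates a
           two-level image", {
  expect_message(m0 <- binarizeSlice(matrix(5, 8, 8)), "constant")
  expect_identical(m0, matrix(FALSE, 8, 8))
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  m <- binarizeSlice(img)
  expect_type(m[1], "logical")
  expect_equal(dim(m), dim(img))
  expect_true(all(m[img == 200]) && !any(m[img == 10]))
  # exhaustive-search Otsu oracle: the chosen split maximizes between-class
  # variance, so the mask is the upper level set of the best threshold
  set.seed(1)
  noisy <- matrix(c(rnorm(60, 0.2, 0.05), rnorm(40, 0.8, 0.05)), 10, 10)
  mask <- binarizeSlice(noisy)
  expect_true(min(noisy[mask]) > max(noisy[!mask])) # upper level set
  best <- sort(noisy)[which.max(vapply(seq_len(99), function(k) {
    s <- sort(noisy); lo <- s[seq_len(k)]; hi <- s[-seq_len(k)]
    k * (100 - k) * (mean(hi) - mean(lo))^2
  }, numeric(1)))]
  expect_true(all(mask == (noisy > best)))
  # fixed threshold mode
  expect_identical(binarizeSlice(img, "fixed", threshold = 100), img > 100)
})

test_that("void extraction matches the brute-force oracle on shaped and
           random masks", {
  # sealed square hole: the r=1 disk (a cross) rounds the 4 hole corners
  sq <- matrix(FALSE, 20, 20); sq[4:16, 4:16] <- TRUE; sq[8:12, 8:12] <- FALSE
  v <- extractVoidComponents(sq, 1, 1)
  expect_equal(length(v), 1)
  expect_equal(sum(v[[1]]), 21)
  expect_identical(v, brute_voids(sq, 1))
  # diamond hole is invariant under the cross
  di <- matrix(FALSE, 20, 20); di[4:16, 4:16] <- TRUE
  for (y in 8:12) for (x in 8:12) if (abs(y - 10) + abs(x - 10) <= 2)
    di[y, x] <- FALSE
  vd <- extractVoidComponents(di, 1, 1)
  expect_equal(sum(vd[[1]]), 13)
  # degenerate masks
  expect_equal(length(extractVoidComponents(matrix(TRUE, 10, 10), 1, 1)), 0)
  expect_equal(length(extractVoidComponents(matrix(FALSE, 10, 10), 1, 1)), 0)
  # random masks, exact equality against the independent implementation
  set.seed(33)
  for (i in 1:6) {
    m <- matrix(runif(32 * 32) < 0.5, 32, 32)
    for (r in c(1, 3)) {
      expect_identical(extractVoidComponents(m, r, 1), brute_voids(m, r),
                       label = sprintf("mask %d radius %d", i, r))
    }
  }
})

test_that("gap sealing requires a large enough disk (oracle-derived
           transition)", {
  ring <- make_ring(t = 5, gap = 7)
  found <- vapply(1:6, function(r) length(extractVoidComponents(ring, r, 1)),
                  integer(1))
  oracle <- vapply(1:6, function(r) length(brute_voids(ring, r)), integer(1))
  expect_identical(found, oracle)
  expect_identical(found, c(0L, 0L, 0L, 0L, 1L, 1L)) # seals at r = 5
})

test_that("default schedule radii follow the 6 um + 5 um x 8 protocol", {
  cfg <- AnalysisConfig()
  expect_equal(diskRadii(cfg), c(6, 11, 16, 21, 26, 31, 36, 41))
  expect_equal(vapply(diskRadii(cfg), microlumen:::.um_to_px,
                      integer(1), pixel_size = 1),
               c(6L, 11L, 16L, 21L, 26L, 31L, 36L, 41L))
  # sub-pixel radii floor at 1 px; round-half-up pinning
  expect_equal(microlumen:::.um_to_px(0.2, 1), 1L)
  expect_equal(microlumen:::.um_to_px(2.5, 1), 3L)
  expect_equal(microlumen:::.um_to_px(6, 2), 3L)
})

test_that("superimposed detection finds sealed and gapped voids with the
           right first iterations", {
  expect_equal(length(detectCandidateLumens(matrix(FALSE, 30, 30),
                                            AnalysisConfig(), 1)), 0)
  # one sealed big ring + one with an 8-px gap, side by side
  m <- matrix(FALSE, 140, 270)
  m[7:133, 7:133] <- make_big_ring(127, rh = 45, t = 10, gap = 0)
  m[7:133, 137:263] <- make_big_ring(127, rh = 45, t = 10, gap = 20)
  cands <- detectCandidateLumens(m, AnalysisConfig(), 1)
  expect_equal(length(cands), 2)
  iters <- sort(vapply(cands, function(c) c@firstDetectIteration, integer(1)))
  expect_equal(iters[1], 0L)     # sealed void found by the 6 um disk
  expect_gt(iters[2], 0L)        # gapped void needs a later iteration
  # each candidate's area equals its maximum single-iteration area
  for (cd in cands) {
    per_iter <- vapply(diskRadii(AnalysisConfig()), function(r) {
      comps <- extractVoidComponents(m, r, 1)
      hit <- vapply(comps, function(cm) any(cm & cd@mask), logical(1))
      if (!any(hit)) 0L else max(vapply(comps[hit], sum, integer(1)))
    }, integer(1))
    expect_equal(cd@areaPx, max(per_iter))
  }
})

test_that("detection is monotone across iterations once a void appears", {
  for (gap in c(4, 10, 16)) {
    m <- make_big_ring(gap = gap)
    detected <- vapply(diskRadii(AnalysisConfig()), function(r)
      length(extractVoidComponents(m, r, 1)) > 0, logical(1))
    if (any(detected))
      expect_true(all(detected[seq(which(detected)[1], length(detected))]),
                  label = sprintf("gap %d monotone", gap))
  }
})

test_that("background discard and area conservation hold", {
  set.seed(5)
  m <- matrix(runif(40 * 40) < 0.45, 40, 40)
  cands <- detectCandidateLumens(m, AnalysisConfig(diskInit = 2,
                                                   diskIncrement = 1,
                                                   diskIterations = 3L,
                                                   minCandidateArea = 1), 1)
  if (length(cands)) {
    # corner-containing background component is never returned
    expect_true(all(vapply(cands, function(c) !c@mask[1, 1], logical(1))))
    expect_lt(sum(vapply(cands, function(c) c@areaPx, integer(1))),
              length(m))
  }
  succeed()
})

test_that("re-running single-radius detection on the closed foreground is
           a fixed point", {
  m <- make_ring(t = 5, gap = 7)
  cfg <- AnalysisConfig(diskInit = 5, diskIncrement = 0,
                        diskIterations = 1L, minCandidateArea = 1)
  c1 <- detectCandidateLumens(m, cfg, 1)
  c2 <- detectCandidateLumens(binaryClose(m, 5, 1), cfg, 1)
  expect_equal(length(c1), length(c2))
  expect_identical(c1[[1]]@mask, c2[[1]]@mask)
})

test_that("candidate areas in um^2 are resolution-consistent", {
  mk_phys <- function(ps) {
    n <- round(96 / ps)
    px <- function(um) round(um / ps)
    m <- matrix(FALSE, n, n)
    m[px(24):(n - px(24) + 1), px(24):(n - px(24) + 1)] <- TRUE
    m[px(34):(n - px(34) + 1), px(34):(n - px(34) + 1)] <- FALSE
    m
  }
  a1 <- detectCandidateLumens(mk_phys(1), AnalysisConfig(), 1)
  a2 <- detectCandidateLumens(mk_phys(2), AnalysisConfig(), 2)
  expect_equal(length(a1), 1)
  expect_equal(length(a2), 1)
  expect_lt(abs(a1[[1]]@areaUm2 - a2[[1]]@areaUm2) / a1[[1]]@areaUm2, 0.15)
})

test_that("patch preparation crops, pads and normalizes", {
  sp <- StackSpec(dim = c(9L, 96L, 96L), tissueRadius = 28, nNuclei = 6L,
                  seed = 13L,
                  lumens = list(list(center = c(0, 0, 0),
                                     semiAxes = c(9, 8, 8), gapWidth = 0)))
  sim <- generateMicrotissueStack(sp)
  z <- 5L
  mask <- binarizeSlice(getSlice(sim$stack, z, "actin"))
  cands <- detectCandidateLumens(mask, AnalysisConfig(), 1, z = z)
  inLumen <- vapply(cands, function(cd)
    sum(cd@mask & sim$truth@labels[, , z] > 0) / cd@areaPx > 0.5, logical(1))
  cd <- cands[inLumen][[1]]
  p <- preparePatch(cd, sim$stack, dilation = 4, patchSize = 32L)
  expect_equal(dim(p@patch), c(32, 32, 2))
  expect_gte(min(p@patch), 0)
  expect_lte(max(p@patch), 1)
  # dilation monotonicity: larger dilation crops a superset region
  p1 <- preparePatch(cd, sim$stack, dilation = 2, patchSize = 32L)
  p2 <- preparePatch(cd, sim$stack, dilation = 6, patchSize = 32L)
  expect_true(all(p2@bbox[1:2] <= p1@bbox[1:2]) &&
              all(p2@bbox[3:4] >= p1@bbox[3:4]))
  # candidate touching the border still yields a full-size patch
  edge <- matrix(FALSE, 40, 40); edge[1:6, 1:6] <- TRUE
  cdE <- make_candidate(edge, 1L)
  vox <- array(runif(40 * 40 * 1 * 2), dim = c(40, 40, 1, 2))
  pe <- preparePatch(cdE, ZStack(vox, 1, 5), dilation = 4, patchSize = 32L)
  expect_equal(dim(pe@patch), c(32, 32, 2))
})

test_that("representative slice is the largest-area slice with low-index
           ties", {
  one <- ZStack(array(runif(50 * 50 * 1 * 2), c(50, 50, 1, 2)), 1, 5)
  expect_equal(selectRepresentativeSlice(one), 1L)
  sp <- StackSpec(dim = c(11L, 96L, 96L), tissueRadius = 25, zStep = 5,
                  nNuclei = 5L, lumens = list(), seed = 4L)
  sim <- generateMicrotissueStack(sp)
  expect_equal(selectRepresentativeSlice(sim$stack), 6L) # equatorial slice
  # tie -> lowest index: two identical informative slices
  v <- array(0.05, dim = c(60, 60, 3, 2))
  v[20:40, 20:40, 2, 2] <- 0.9
  v[20:40, 20:40, 3, 2] <- 0.9
  expect_equal(selectRepresentativeSlice(ZStack(v, 1, 5)), 2L)
})

test_that("nuclei counting is exact on planted non-overlapping nuclei and
           ignores specks", {
  blank <- ZStack(array(0.02, dim = c(64, 64, 3, 2)), 1, 5)
  expect_equal(countNuclei(blank), 0L)
  sp <- StackSpec(dim = c(25L, 256L, 256L), nNuclei = 30L, seed = 8L,
                  lumens = list(), noiseSd = 0.02)
  sim <- generateMicrotissueStack(sp)
  expect_equal(countNuclei(sim$stack), 30L)
  # single-pixel bright specks below the area floor do not change the count
  vox <- sim$stack@voxels
  set.seed(1)
  for (i in 1:15) {
    y <- sample(5:250, 1); x <- sample(5:250, 1)
    vox[y, x, 3, 1] <- 1
  }
  withSpecks <- ZStack(vox, pixelSize = 1, zStep = 5)
  expect_equal(countNuclei(withSpecks), 30L)
})
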