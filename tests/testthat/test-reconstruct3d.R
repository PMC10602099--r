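# Grouping, alpha-hull reconstruction and microtissue summaries.

box_cand <- function(y0, x0, y1, x1, z, n = 40) {
  m <- matrix(FALSE, n, n); m[y0:y1, x0:x1] <- TRUE
  make_candidate(m, z)
}

test_that("grouping links overlapping boxes across adjacent slices and
           splits at gaps", {
  expect_equal(length(groupLumens(list(box_cand(5, 5, 10, 10, 3L)))), 1)
  # z = 3,4,5 overlapping -> one group
  g1 <- groupLumens(list(box_cand(5, 5, 10, 10, 3L),
                         box_cand(6, 6, 11, 11, 4L),
                         box_cand(5, 5, 10, 10, 5L)))
  expect_equal(length(g1), 1)
  expect_equal(length(g1[[1]]@members), 3)
  # z = 3,4 and 6,7 with slice 5 absent -> two groups (gapTolerance 0)
  g2 <- groupLumens(list(box_cand(5, 5, 10, 10, 3L),
                         box_cand(5, 5, 10, 10, 4L),
                         box_cand(5, 5, 10, 10, 6L),
                         box_cand(5, 5, 10, 10, 7L)))
  expect_equal(length(g2), 2)
  # gapTolerance 1 bridges the single missing slice
  g3 <- groupLumens(list(box_cand(5, 5, 10, 10, 3L),
                         box_cand(5, 5, 10, 10, 4L),
                         box_cand(5, 5, 10, 10, 6L)), gapTolerance = 1L)
  expect_equal(length(g3), 1)
  # xy-disjoint stacks over the same z range -> two groups
  g4 <- groupLumens(list(box_cand(2, 2, 8, 8, 3L),
                         box_cand(2, 2, 8, 8, 4L),
                         box_cand(20, 20, 28, 28, 3L),
                         box_cand(20, 20, 28, 28, 4L)))
  expect_equal(length(g4), 2)
  # edge contact counts as overlap (closed rectangles)
  g5 <- groupLumens(list(box_cand(5, 5, 10, 10, 3L),
                         box_cand(10, 10, 15, 15, 4L)))
  expect_equal(length(g5), 1)
  g6 <- groupLumens(list(box_cand(5, 5, 10, 10, 3L),
                         box_cand(11, 11, 15, 15, 4L)))
  expect_equal(length(g6), 2)
})

test_that("inserting one missing slice inside a lumen's span doubles its
           group count", {
  cands <- sphere_candidates(15)          # slices 2..6 carry masks
  zs <- vapply(cands, function(c) c@z, integer(1))
  mid <- zs[ceiling(length(zs) / 2)]
  expect_equal(length(groupLumens(cands)), 1)
  expect_equal(length(groupLumens(cands[zs != mid])), 2)
})

test_that("single-slice groups use the exact extrusion convention", {
  m <- matrix(FALSE, 20, 20); m[5:10, 5:12] <- TRUE
  g <- groupLumens(list(make_candidate(m, 4L)))[[1]]
  L <- reconstructLumen(g, pixelSize = 1, zStep = 5)
  expect_equal(L@volume, sum(m) * 1 * 5)
  expect_true(is.na(L@alpha))
  expect_equal(L@sliceSpan, c(4L, 4L))
  # pixel size scales the area quadratically
  L2 <- reconstructLumen(g, pixelSize = 2, zStep = 5)
  expect_equal(L2@volume, sum(m) * 4 * 5)
})

test_that("alpha-hull volumes track analytic spheres and similarity
           scaling", {
  g20 <- groupLumens(sphere_candidates(20))[[1]]
  L20 <- reconstructLumen(g20, 1, 5)
  expect_lt(abs(L20@volume - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.15)
  expect_gt(L20@alpha, 0)
  # doubling all coordinates: volume x8, surface x4 (mesh tolerance 12%)
  g40 <- groupLumens(sphere_candidates(40))[[1]]
  L40 <- reconstructLumen(g40, 1, 5)
  expect_lt(abs(L40@volume / L20@volume - 8) / 8, 0.12)
  expect_lt(abs(L40@surfaceArea / L20@surfaceArea - 4) / 4, 0.12)
})

test_that("volume does not decrease when semi-axes grow, and anisotropic
           resampling agrees", {
  vols <- vapply(c(10, 14, 18, 22), function(r)
    reconstructLumen(groupLumens(sphere_candidates(r))[[1]], 1, 5)@volume,
    numeric(1))
  expect_true(all(diff(vols) > 0))
  # same sphere at z-steps 5 and 2.5 um
  v5 <- reconstructLumen(groupLumens(sphere_candidates(20, zstep = 5))[[1]],
                         1, 5)@volume
  v25 <- reconstructLumen(groupLumens(sphere_candidates(20,
                                                        zstep = 2.5))[[1]],
                          1, 2.5)@volume
  expect_lt(abs(v5 - v25) / v25, 0.10)
})

test_that("fixed-alpha policy is honoured and recorded", {
  g <- groupLumens(sphere_candidates(15))[[1]]
  L <- reconstructLumen(g, 1, 5, alphaPolicy = "fixed", alpha = 12)
  expect_equal(L@alpha, 12)
  expect_error(reconstructLumen(g, 1, 5, alphaPolicy = "fixed"),
               "alpha must be")
})

test_that("microtissue summaries satisfy their invariants", {
  r0 <- summarizeMicrotissue(list(), "empty")
  expect_equal(lumenCount(r0), 0L)
  expect_equal(totalVolume(r0), 0)
  mk <- function(vol) methods::new("Lumen3D", groupId = "g", alpha = 1,
    points = matrix(0, 1, 3), volume = vol, surfaceArea = vol / 2,
    sliceSpan = c(1L, 2L))
  r <- summarizeMicrotissue(list(mk(100), mk(50)), "m")
  expect_equal(lumenCount(r), 2L)
  expect_equal(totalVolume(r), 150)
  rPerm <- summarizeMicrotissue(list(mk(50), mk(100)), "m")
  expect_equal(totalVolume(rPerm), totalVolume(r))
  expect_equal(sort(lumenVolume(rPerm)), sort(lumenVolume(r)))
})

test_that("full pipeline with the oracle classifier recovers lumen counts
           and ellipsoid volumes on noiseless stacks", {
  for (k in c(1, 3)) {
    sim <- generateMicrotissueStack(k_lumen_spec(k, seed = 40 + k))
    res <- analyzeLumens(sim$stack, oracleClassifier(sim$truth),
                         AnalysisConfig(), id = paste0("k", k))
    expect_equal(lumenCount(res$result), k)
    got <- sort(lumenVolume(res$result))
    want <- sort(sim$truth@volumes)
    expect_true(all(abs(got - want) / want < 0.15),
                label = sprintf("k=%d volumes within 15%%", k))
  }
})
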