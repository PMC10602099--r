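# True/false lumen classification. The shipped default scores engineered
# shape/intensity descriptors of each candidate patch with a random forest;
# any callable model (e.g. a CNN wrapper) can be plugged in through the
# same interface, and an oracle backed by a ground-truth label volume
# supports geometry-only evaluation of the pipeline.

# Engineered descriptors of one [size, size, 2] patch (nuclei, actin).
# The central dark blob is the putative void; a true lumen shows an
# enclosed dark void (low border contact) ringed by bright actin.
.patch_features <- function(patch) {
  ach <- patch[, , 2]
  nch <- patch[, , 1]
  n <- nrow(ach)
  rng <- range(ach)
  feats <- c(voidAreaFrac = 0, borderContact = 1, extent = 0,
             eccentricity = 0, rimContrast = 0, rimBrightFrac = 0,
             voidActinMean = 1, voidNucleiMean = 1, actinSd = sd(ach))
  if (diff(rng) == 0) return(feats)
  th <- EBImage::otsu(ach, range = c(0, 1), levels = 256L)
  dark <- ach <= th
  if (!any(dark)) return(feats)
  lab <- labelComponents(dark, connectivity = 4)
  ctr <- lab[round(n / 2), round(n / 2)]
  if (ctr == 0) { # fall back to the largest dark component
    sizes <- tabulate(lab, nbins = max(lab))
    ctr <- which.max(sizes)
  }
  v <- lab == ctr
  idx <- which(v, arr.ind = TRUE)
  area <- nrow(idx)
  onBorder <- sum(idx[, 1] == 1 | idx[, 1] == n |
                  idx[, 2] == 1 | idx[, 2] == n)
  bboxArea <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  myy <- mean((idx[, 1] - cy)^2); mxx <- mean((idx[, 2] - cx)^2)
  mxy <- mean((idx[, 1] - cy) * (idx[, 2] - cx))
  tr <- (myy + mxx) / 2
  det <- sqrt(max(0, ((myy - mxx) / 2)^2 + mxy^2))
  l1 <- tr + det; l2 <- max(tr - det, 1e-12)
  rim <- binaryDilate(v, 2.5) & !v
  feats["voidAreaFrac"] <- area / n^2
  feats["borderContact"] <- onBorder / max(1, .mask_perimeter(v))
  feats["extent"] <- area / bboxArea
  feats["eccentricity"] <- sqrt(max(0, 1 - l2 / l1))
  feats["rimContrast"] <- mean(ach[rim]) - mean(ach[v])
  feats["rimBrightFrac"] <- mean(ach[rim] > 0.6)
  feats["voidActinMean"] <- mean(ach[v])
  feats["voidNucleiMean"] <- mean(nch[v])
  feats
}

# number of mask pixels with at least one 4-neighbour outside the mask
# (array borders count as outside)
.mask_perimeter <- function(v) {
  p <- rbind(FALSE, v[-nrow(v), ]) & rbind(v[-1, ], FALSE) &
       cbind(FALSE, v[, -ncol(v)]) & cbind(v[, -1], FALSE)
  sum(v & !p)
}

#' Compute engineered patch descriptors
#'
#' The feature vector behind the default classifier: void area fraction,
#' border-contact fraction of the central dark blob, extent, eccentricity,
#' actin rim contrast and bright-rim fraction, interior actin/nuclei means
#' and overall actin sd.
#'
#' @param patches list of [CandidatePatch-class] (or bare arrays).
#' @return numeric matrix, one row per patch.
#' @export
patchFeatures <- function(patches) {
  rows <- lapply(patches, function(p) {
    arr <- if (is(p, "CandidatePatch")) p@patch else p
    .patch_features(arr)
  })
  do.call(rbind, rows)
}

#' Train a lumen classifier
#'
#' Default `kind = "features"`: engineered patch descriptors
#' ([patchFeatures()]) scored by a random forest; training is deterministic
#' given `seed`. `kind = "callable"` wraps a user model
#' (`function(patches) -> probability vector`), so an external network can
#' stand behind the same interface.
#'
#' @param patches list of [CandidatePatch-class].
#' @param labels logical (or coercible) vector, `TRUE` = true lumen.
#' @param kind `"features"` or `"callable"`.
#' @param model the callable, when `kind = "callable"`.
#' @param threshold decision threshold (default 0.5).
#' @param seed training seed.
#' @param nTrees forest size for the default kind.
#' @return A [LumenClassifier-class].
#' @export
trainLumenClassifier <- function(patches, labels, kind = "features",
                                 model = NULL, threshold = 0.5, seed = 1L,
                                 nTrees = 200L) {
  if (kind == "callable") {
    stopifnot(is.function(model))
    ps <- if (length(patches)) dim(patches[[1]]@patch)[1] else NA_integer_
    return(new("LumenClassifier", kind = "callable", model = model,
               threshold = threshold, seed = as.integer(seed),
               patchSize = as.integer(ps)))
  }
  if (length(patches) == 0) stop("empty training set")
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("need both classes in the training set")
  x <- as.data.frame(patchFeatures(patches))
  y <- factor(ifelse(labels, "lumen", "not"), levels = c("not", "lumen"))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = y, ntree = nTrees)
  new("LumenClassifier", kind = "features", model = rf,
      threshold = threshold, seed = as.integer(seed),
      patchSize = as.integer(dim(patches[[1]]@patch)[1]))
}

#' Harvest labeled training patches from synthetic stacks
#'
#' Emulates assembling a marked training set the way it is done on real
#' data: seeded synthetic microtissue stacks are pushed through the
#' detection pipeline, every candidate is labeled by its overlap with the
#' ground-truth lumen volume, and its prepared patch is collected. This
#' yields patches with the exact cropping, resizing and normalization
#' statistics the classifier will see at inference time — including the
#' hard negatives (tissue cross-sections, background voids) that a purely
#' stylized patch generator under-represents.
#'
#' @param nStacks number of stacks to harvest.
#' @param seed integer seed (stack `i` uses `seed + i`).
#' @param config an [AnalysisConfig-class] (patch geometry must match the
#'   analysis configuration the classifier will be used with).
#' @return `list(patches = list of CandidatePatch, labels = logical)`.
#' @export
harvestTrainingPatches <- function(nStacks = 2L, seed = 1L,
                                   config = AnalysisConfig()) {
  patches <- list(); labels <- logical(0)
  pos <- list(c(-13, -11, 0), c(14, 11, 0), c(-2, 13, -8))
  ax <- list(c(11, 10, 9), c(9, 10, 8), c(9, 8, 8))
  gaps <- c(0, 6, 0)
  for (s in seq_len(nStacks)) {
    k <- 2L + (s %% 2L)
    spec <- StackSpec(dim = c(17L, 176L, 176L), tissueRadius = 40,
                      nNuclei = 20L, seed = as.integer(seed) + s,
                      lumens = lapply(seq_len(k), function(j)
                        list(center = pos[[j]], semiAxes = ax[[j]],
                             gapWidth = gaps[j])))
    sim <- generateMicrotissueStack(spec)
    for (z in seq_len(nSlices(sim$stack))) {
      m <- suppressMessages(binarizeSlice(
        getSlice(sim$stack, z, "actin"),
        method = config@binarizeMethod,
        threshold = config@binarizeThreshold))
      for (cd in detectCandidateLumens(m, config,
                                       pixelSize(sim$stack), z = z)) {
        patches[[length(patches) + 1]] <-
          preparePatch(cd, sim$stack, config@patchDilation,
                       config@patchSize)
        labels <- c(labels,
                    sum(cd@mask & sim$truth@labels[, , z] > 0) /
                      cd@areaPx >= 0.5)
      }
    }
  }
  list(patches = patches, labels = labels)
}

#' Oracle classifier from ground truth
#'
#' Scores a candidate by the fraction of its mask overlapping any lumen
#' label of a [GroundTruth-class] volume. Used to isolate geometry errors
#' from classifier errors on synthetic stacks.
#'
#' @param truth a [GroundTruth-class].
#' @param threshold overlap fraction above which a candidate is "true".
#' @return A [LumenClassifier-class] of kind `"oracle"`.
#' @export
oracleClassifier <- function(truth, threshold = 0.5) {
  stopifnot(is(truth, "GroundTruth"))
  new("LumenClassifier", kind = "oracle", model = truth@labels,
      threshold = threshold, seed = 0L, patchSize = NA_integer_)
}

#' @describeIn trainLumenClassifier classify candidate patches. Returns a
#'   data.frame with one row per input (same order): `probability` in
#'   `[0, 1]` and logical `label` (`probability >= threshold`). The oracle
#'   kind requires `candidates` (masks + slice indices) instead of patch
#'   pixels.
#' @param candidates list of [CandidateLumen2D-class] (oracle kind only).
#' @export
setMethod("classifyCandidates", "LumenClassifier",
  function(model, patches, candidates = NULL) {
    if (model@kind == "oracle") {
      if (is.null(candidates)) stop("oracle classifier needs candidates")
      prob <- vapply(candidates, function(cd) {
        sl <- model@model[, , cd@z]
        sum(cd@mask & sl > 0) / cd@areaPx
      }, numeric(1))
    } else if (length(patches) == 0) {
      prob <- numeric(0)
    } else if (model@kind == "callable") {
      prob <- as.numeric(model@model(patches))
    } else {
      sizes <- vapply(patches, function(p)
        dim(if (is(p, "CandidatePatch")) p@patch else p)[1], integer(1))
      if (any(sizes != model@patchSize))
        stop("patch size mismatch: model expects ", model@patchSize, " px")
      x <- as.data.frame(patchFeatures(patches))
      prob <- unname(predict(model@model, x, type = "prob")[, "lumen"])
    }
    data.frame(probability = prob, label = prob >= model@threshold)
  })

setMethod("show", "LumenClassifier", function(object) {
  cat("LumenClassifier (", object@kind, "), threshold ",
      object@threshold, "\n", sep = "")
})
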