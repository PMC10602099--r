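# Central S4 classes. Image-side containers hold calibrated voxel data and
# per-stage detection results; profiling-side containers wrap
# SummarizedExperiment for the samples x features currency.

#' ZStack: calibrated two-channel 3D image
#'
#' Voxel intensities of a microtissue z-stack with the physical calibration
#' required to convert pixel measurements to micrometres. The voxel array is
#' indexed `[y, x, z, channel]`; channels are named and normalized to the
#' order `nuclei`, `actin`.
#'
#' @slot voxels numeric array `[y, x, z, channel]`, intensities in `[0, 1]`.
#' @slot channels character vector of channel names (in array order).
#' @slot pixelSize lateral pixel size, um per pixel (x = y).
#' @slot zStep axial distance between consecutive slices, um.
#' @exportClass ZStack
setClass("ZStack",
  representation(voxels = "array", channels = "character",
                 pixelSize = "numeric", zStep = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@voxels)
    if (length(d) != 4) msg <- c(msg, "voxels must be a 4D [y, x, z, channel] array")
    else {
      if (d[3] < 1) msg <- c(msg, "need at least one slice")
      if (d[4] != length(object@channels))
        msg <- c(msg, "channel count must match channel names")
    }
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (length(object@zStep) != 1 || object@zStep <= 0)
      msg <- c(msg, "zStep must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' AnalysisConfig: parameters of the lumen pipeline
#'
#' Gathers every tunable of the slice pipeline, classification and 3D
#' reconstruction. Defaults encode the published acquisition and closing
#' schedule: a 6 um initial disk grown by 5 um for 8 iterations, at a 5 um
#' z-step.
#'
#' @slot diskInit initial closing-disk radius, um.
#' @slot diskIncrement per-iteration radius increment, um.
#' @slot diskIterations number of closing iterations (>= 1).
#' @slot binarizeMethod `"otsu"` or `"fixed"`.
#' @slot binarizeThreshold threshold for `"fixed"` (ignored for `"otsu"`).
#' @slot minCandidateArea minimum candidate area, px^2.
#' @slot patchDilation candidate dilation before patch cropping, um.
#' @slot patchSize classifier patch side length, px.
#' @slot gapTolerance z-gap (slices) tolerated inside one 3D lumen group.
#' @slot alphaPolicy `"auto"` (critical alpha) or a fixed numeric alpha (um)
#'   stored in `alphaFixed`.
#' @slot alphaFixed fixed alpha in um (`NA` under `"auto"`).
#' @slot classifierThreshold probability cutoff for "true" lumens.
#' @slot seed integer seed forwarded to seeded stages.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(diskInit = "numeric", diskIncrement = "numeric",
                 diskIterations = "integer", binarizeMethod = "character",
                 binarizeThreshold = "numeric", minCandidateArea = "numeric",
                 patchDilation = "numeric", patchSize = "integer",
                 gapTolerance = "integer", alphaPolicy = "character",
                 alphaFixed = "numeric", classifierThreshold = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@diskInit <= 0) msg <- c(msg, "diskInit must be > 0")
    if (object@diskIncrement < 0) msg <- c(msg, "diskIncrement must be >= 0")
    if (object@diskIterations < 1L) msg <- c(msg, "diskIterations must be >= 1")
    if (!object@binarizeMethod %in% c("otsu", "fixed"))
      msg <- c(msg, "binarizeMethod must be 'otsu' or 'fixed'")
    if (object@patchDilation <= 0) msg <- c(msg, "patchDilation must be > 0")
    if (object@patchSize < 8L) msg <- c(msg, "patchSize must be >= 8 px")
    if (object@gapTolerance < 0L) msg <- c(msg, "gapTolerance must be >= 0")
    if (!object@alphaPolicy %in% c("auto", "fixed"))
      msg <- c(msg, "alphaPolicy must be 'auto' or 'fixed'")
    if (object@alphaPolicy == "fixed" &&
        (is.na(object@alphaFixed) || object@alphaFixed <= 0))
      msg <- c(msg, "alphaFixed must be > 0 under alphaPolicy 'fixed'")
    if (object@classifierThreshold <= 0 || object@classifierThreshold >= 1)
      msg <- c(msg, "classifierThreshold must lie in (0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' CandidateLumen2D: one void region on one z-slice
#'
#' A single 4-connected void component surviving the closing schedule, with
#' its slice-shaped mask and detection metadata. `z` is 1-based in memory;
#' serialized manifests are 0-based.
#'
#' @slot z slice index (1-based).
#' @slot mask logical matrix shaped like the slice; `TRUE` = void pixel.
#' @slot areaPx area in pixels.
#' @slot areaUm2 area in um^2.
#' @slot bbox integer `c(y0, x0, y1, x1)`, 1-based closed bounds.
#' @slot centroid numeric `c(y, x)` centroid (1-based pixel coordinates).
#' @slot firstDetectIteration 0-based index of the earliest closing
#'   iteration at which any pixel of this candidate was detected.
#' @exportClass CandidateLumen2D
setClass("CandidateLumen2D",
  representation(z = "integer", mask = "matrix", areaPx = "integer",
                 areaUm2 = "numeric", bbox = "integer", centroid = "numeric",
                 firstDetectIteration = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@areaPx != sum(object@mask))
      msg <- c(msg, "areaPx must equal the number of TRUE pixels")
    if (length(object@bbox) != 4) msg <- c(msg, "bbox must be c(y0, x0, y1, x1)")
    if (is.null(msg)) TRUE else msg
  })

#' CandidatePatch: classifier-ready crop around a candidate
#'
#' @slot id candidate identifier.
#' @slot patch numeric array `[patchSize, patchSize, 2]` (nuclei, actin),
#'   per-channel min-max normalized to `[0, 1]`.
#' @slot z source slice (1-based).
#' @slot bbox source bounding box, 1-based closed `c(y0, x0, y1, x1)` of the
#'   dilated candidate.
#' @exportClass CandidatePatch
setClass("CandidatePatch",
  representation(id = "character", patch = "array", z = "integer",
                 bbox = "integer"))

#' LumenGroup: z-ordered 2D lumens forming one 3D lumen
#'
#' @slot members list of [CandidateLumen2D-class] ordered by
#'   non-decreasing z.
#' @slot id group identifier.
#' @exportClass LumenGroup
setClass("LumenGroup",
  representation(members = "list", id = "character"),
  validity = function(object) {
    if (length(object@members) == 0) return("group must be non-empty")
    zs <- vapply(object@members, function(m) m@z, integer(1))
    if (is.unsorted(zs)) return("members must be ordered by z")
    TRUE
  })

#' Lumen3D: reconstructed 3D lumen
#'
#' @slot groupId source group id.
#' @slot points numeric matrix (n x 3) of boundary points, um, columns
#'   `x, y, z`.
#' @slot alpha alpha value used for reconstruction, um (`NA` for
#'   single-slice extrusions).
#' @slot volume lumen volume, um^3.
#' @slot surfaceArea lumen surface area, um^2.
#' @slot sliceSpan integer `c(zmin, zmax)` (1-based).
#' @exportClass Lumen3D
setClass("Lumen3D",
  representation(groupId = "character", points = "matrix", alpha = "numeric",
                 volume = "numeric", surfaceArea = "numeric",
                 sliceSpan = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@volume < 0) msg <- c(msg, "volume must be >= 0")
    if (object@surfaceArea < 0) msg <- c(msg, "surfaceArea must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' MicrotissueResult: per-microtissue lumen summary
#'
#' @slot id microtissue identifier.
#' @slot lumenCount number of reconstructed lumens.
#' @slot volumes per-lumen volumes, um^3.
#' @slot surfaceAreas per-lumen surface areas, um^2.
#' @slot totalVolume sum of per-lumen volumes, um^3.
#' @exportClass MicrotissueResult
setClass("MicrotissueResult",
  representation(id = "character", lumenCount = "integer",
                 volumes = "numeric", surfaceAreas = "numeric",
                 totalVolume = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@lumenCount != length(object@volumes))
      msg <- c(msg, "lumenCount must equal length(volumes)")
    if (length(object@volumes) != length(object@surfaceAreas))
      msg <- c(msg, "volumes and surfaceAreas must have equal length")
    if (any(object@volumes < 0)) msg <- c(msg, "volumes must be >= 0")
    if (abs(object@totalVolume - sum(object@volumes)) >
        1e-6 * max(1, sum(object@volumes)))
      msg <- c(msg, "totalVolume must equal sum(volumes)")
    if (is.null(msg)) TRUE else msg
  })

#' LumenClassifier: pluggable true/false lumen classifier
#'
#' The shipped default (`kind = "features"`) scores engineered
#' shape/intensity patch descriptors with a random forest; `kind =
#' "callable"` wraps any `function(patches) -> probability` so an external
#' (e.g. deep) model can be plugged in; `kind = "oracle"` scores candidates
#' against a ground-truth label volume.
#'
#' @slot kind one of `"features"`, `"callable"`, `"oracle"`.
#' @slot model fitted model object, callable, or ground-truth array.
#' @slot threshold decision threshold in (0, 1); default 0.5.
#' @slot seed training seed.
#' @slot patchSize patch side length the model expects (px).
#' @exportClass LumenClassifier
setClass("LumenClassifier",
  representation(kind = "character", model = "ANY", threshold = "numeric",
                 seed = "integer", patchSize = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("features", "callable", "oracle"))
      msg <- c(msg, "kind must be 'features', 'callable' or 'oracle'")
    if (object@threshold <= 0 || object@threshold >= 1)
      msg <- c(msg, "threshold must lie in (0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' StackSpec: recipe for a synthetic microtissue z-stack
#'
#' @slot dim integer `c(z, y, x)` stack shape.
#' @slot pixelSize um per pixel.
#' @slot zStep um between slices.
#' @slot tissueRadius microtissue radius, um.
#' @slot nNuclei number of nuclei.
#' @slot nucleusRadius nucleus radius, um.
#' @slot lumens list; each element `list(center = c(x, y, z) um relative to
#'   tissue center, semiAxes = c(a, b, c) um, gapWidth = um)`.
#' @slot wallThickness actin wall thickness, um.
#' @slot noiseSd additive Gaussian noise sd, fraction of dynamic range.
#' @slot seed integer; fixes all randomness.
#' @exportClass StackSpec
setClass("StackSpec",
  representation(dim = "integer", pixelSize = "numeric", zStep = "numeric",
                 tissueRadius = "numeric", nNuclei = "integer",
                 nucleusRadius = "numeric", lumens = "list",
                 wallThickness = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@dim) != 3 || any(object@dim < 1))
      msg <- c(msg, "dim must be positive c(z, y, x)")
    if (object@pixelSize <= 0 || object@zStep <= 0)
      msg <- c(msg, "calibration must be positive")
    if (object@tissueRadius <= 0) msg <- c(msg, "tissueRadius must be > 0")
    half <- c(object@dim[3] - 1, object@dim[2] - 1) / 2 * object@pixelSize
    if (object@tissueRadius > min(half))
      msg <- c(msg, "stack shape too small for tissue radius")
    for (lu in object@lumens) {
      if (lu$gapWidth < 0) msg <- c(msg, "gap width must be >= 0")
      reach <- sqrt(sum(lu$center^2)) + max(lu$semiAxes) + object@wallThickness
      if (reach > object@tissueRadius)
        msg <- c(msg, "lumen (wall included) must lie inside the tissue")
    }
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' GroundTruth: known answers for a synthetic stack
#'
#' @slot labels integer array `[y, x, z]`; 0 background, k > 0 marks voxels
#'   of lumen k's interior (labels are assigned pre-noise and are unaffected
#'   by the noise level).
#' @slot volumes analytic per-lumen ellipsoid volumes (4/3 pi a b c), um^3.
#' @slot nucleiCenters numeric matrix (n x 3) of nucleus centers, um,
#'   columns `x, y, z`.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(labels = "array", volumes = "numeric",
                 nucleiCenters = "matrix"))

#' TableSpec: recipe for a synthetic multi-class feature table
#'
#' @slot groups group names (dose levels), in order.
#' @slot groupSizes samples per group.
#' @slot nFeatures total number of features.
#' @slot nDifferential number of planted differential features.
#' @slot effectProfile per-group mean shift (in units of the feature sd) for
#'   planted features; length = number of groups. Monotone by default, but
#'   any profile (e.g. non-monotone) is accepted.
#' @slot noiseSd per-feature noise sd.
#' @slot orientationFraction fraction of features named with an
#'   `"orientation"` token (dummy features later dropped by the workflow).
#' @slot seed integer seed.
#' @exportClass TableSpec
setClass("TableSpec",
  representation(groups = "character", groupSizes = "integer",
                 nFeatures = "integer", nDifferential = "integer",
                 effectProfile = "numeric", noiseSd = "numeric",
                 orientationFraction = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@groupSizes) != length(object@groups))
      msg <- c(msg, "groupSizes must match groups")
    if (length(object@effectProfile) != length(object@groups))
      msg <- c(msg, "effectProfile length must equal the number of groups")
    if (object@nDifferential > object@nFeatures)
      msg <- c(msg, "nDifferential cannot exceed nFeatures")
    if (object@orientationFraction < 0 || object@orientationFraction >= 1)
      msg <- c(msg, "orientationFraction must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' FeatureTable: samples x features matrix with dose-group labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay holds
#' features in rows and samples in columns, with a mandatory `group` column
#' in `colData`. Constructed from the more natural samples x features
#' orientation by [FeatureTable()].
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
      msg <- c(msg, "colData must contain a 'group' column")
    else if (anyNA(SummarizedExperiment::colData(object)$group))
      msg <- c(msg, "group labels must not be missing")
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
      msg <- c(msg, "feature names must be present and unique")
    if (is.null(msg)) TRUE else msg
  })

#' OplsModel: fitted OPLS-DA model
#'
#' One predictive component against a (centered) one-hot group encoding,
#' with `nOrtho` orthogonal components removed first. Scores of the
#' predictive and orthogonal parts are exactly orthogonal; VIP is normalized
#' so that `mean(VIP^2) = 1`.
#'
#' @slot scores predictive score vector t (one per sample).
#' @slot loadings predictive loading vector p (one per feature).
#' @slot weights predictive weight vector w (one per feature).
#' @slot orthoScores matrix (samples x nOrtho) of orthogonal scores.
#' @slot orthoLoadings matrix (features x nOrtho).
#' @slot orthoWeights matrix (features x nOrtho).
#' @slot vip named per-feature VIP.
#' @slot q2 cross-validated Q2 of the fitted model.
#' @slot nOrtho number of orthogonal components.
#' @slot groups group level names of the response encoding.
#' @slot featureMeans feature centering applied before fitting.
#' @exportClass OplsModel
setClass("OplsModel",
  representation(scores = "numeric", loadings = "numeric",
                 weights = "numeric", orthoScores = "matrix",
                 orthoLoadings = "matrix", orthoWeights = "matrix",
                 vip = "numeric", q2 = "numeric", nOrtho = "integer",
                 groups = "character", featureMeans = "numeric"))

#' RocResult: multi-class ROC summary
#'
#' @slot perClassAuc named one-vs-rest AUC per class.
#' @slot macroAuc arithmetic mean of per-class AUCs.
#' @slot microAuc AUC of pooled one-vs-rest decisions.
#' @slot seed split/training seed.
#' @exportClass RocResult
setClass("RocResult",
  representation(perClassAuc = "numeric", macroAuc = "numeric",
                 microAuc = "numeric", seed = "integer"),
  validity = function(object) {
    aucs <- c(object@perClassAuc, object@macroAuc, object@microAuc)
    if (any(aucs < -1e-9 | aucs > 1 + 1e-9)) return("AUCs must lie in [0, 1]")
    if (abs(object@macroAuc - mean(object@perClassAuc)) > 1e-9)
      return("macroAuc must be the mean of perClassAuc")
    TRUE
  })
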