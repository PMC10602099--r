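# Seeded generator for multi-class feature tables with planted
# dose-responsive differential features, emulating an image-feature matrix
# (hundreds of morphology/texture descriptors across dose groups) at desk
# scale.

#' Construct a TableSpec
#'
#' Defaults emulate a regrouped dose-response profiling table: four groups
#' (control/low/medium/high) of 50 microtissues, 200 features of which 20
#' are differential with a monotone 1-sd-per-step mean shift, alternating
#' in direction across planted features, and 2% of features named with an
#' `orientation` token (dropped by the standard workflow).
#'
#' @param groups group names, in dose order.
#' @param groupSizes samples per group.
#' @param nFeatures total features (including orientation dummies).
#' @param nDifferential planted differential features.
#' @param effectProfile per-group mean shift in sd units (length =
#'   `length(groups)`); monotone by default, any profile accepted.
#' @param noiseSd per-feature noise sd.
#' @param orientationFraction fraction of features named `orientation_*`.
#' @param seed integer seed.
#' @return A [TableSpec-class].
#' @export
TableSpec <- function(groups = c("control", "low", "medium", "high"),
                      groupSizes = rep(50L, length(groups)),
                      nFeatures = 200L, nDifferential = 20L,
                      effectProfile = seq(0, length(groups) - 1),
                      noiseSd = 1, orientationFraction = 0.02,
                      seed = 1L) {
  new("TableSpec", groups = as.character(groups),
      groupSizes = as.integer(groupSizes), nFeatures = as.integer(nFeatures),
      nDifferential = as.integer(nDifferential),
      effectProfile = as.numeric(effectProfile),
      noiseSd = as.numeric(noiseSd),
      orientationFraction = as.numeric(orientationFraction),
      seed = as.integer(seed))
}

#' Generate a synthetic feature table
#'
#' Features are drawn i.i.d. Gaussian with sd `noiseSd`; each planted
#' differential feature `j` has its per-group mean shifted by
#' `effectProfile[g] * noiseSd * (-1)^(j+1)` (directions alternate, as real
#' dose-responsive features move both ways). A fraction of features carry
#' an `orientation_` name token and no signal. The same seed reproduces
#' the table exactly.
#'
#' @param spec a [TableSpec-class].
#' @return A [FeatureTable-class]; planted feature names are in
#'   `attr(, "differential")`.
#' @examples
#' ft <- generateFeatureTable(TableSpec(seed = 3L))
#' head(attr(ft, "differential"))
#' @export
generateFeatureTable <- function(spec) {
  stopifnot(is(spec, "TableSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- sum(spec@groupSizes)
  group <- rep(spec@groups, spec@groupSizes)
  gIdx <- rep(seq_along(spec@groups), spec@groupSizes)

  nOrient <- round(spec@orientationFraction * spec@nFeatures)
  nPlain <- spec@nFeatures - nOrient
  if (spec@nDifferential > nPlain)
    stop("not enough non-orientation features for the planted set")
  fnames <- c(sprintf("feat_%04d", seq_len(nPlain)),
              if (nOrient > 0) sprintf("orientation_angle_%02d",
                                       seq_len(nOrient)))
  m <- matrix(rnorm(n * spec@nFeatures, 0, spec@noiseSd), nrow = n,
              dimnames = list(NULL, fnames))
  diffFeatures <- fnames[seq_len(spec@nDifferential)]
  for (j in seq_len(spec@nDifferential)) {
    dirn <- if (j %% 2 == 1) 1 else -1
    m[, j] <- m[, j] + dirn * spec@effectProfile[gIdx] * spec@noiseSd
  }
  ft <- FeatureTable(m, group = group)
  attr(ft, "differential") <- diffFeatures
  ft
}
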