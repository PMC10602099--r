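# Analysis configuration: constructor, YAML reading, CLI-flag overrides.

#' Construct an AnalysisConfig
#'
#' Defaults encode the published pipeline parameters: closing disks start at
#' 6 um and grow by 5 um for 8 iterations; Otsu binarization on the actin
#' channel; candidates below 10 px^2 are dropped; any missing slice splits a
#' 3D group (`gapTolerance = 0`); alpha is chosen automatically (critical
#' alpha, see [reconstructLumen()]); classifier threshold 0.5.
#'
#' @param diskInit initial closing-disk radius, um.
#' @param diskIncrement radius increment per iteration, um.
#' @param diskIterations number of iterations.
#' @param binarizeMethod `"otsu"` or `"fixed"`.
#' @param binarizeThreshold threshold used when `binarizeMethod = "fixed"`.
#' @param minCandidateArea minimum candidate area, px^2.
#' @param patchDilation dilation applied to a candidate before cropping its
#'   classification patch, um.
#' @param patchSize patch side length, px.
#' @param gapTolerance tolerated z-gap (slices) within one 3D lumen.
#' @param alphaPolicy `"auto"` or `"fixed"`.
#' @param alphaFixed fixed alpha, um (required when `alphaPolicy = "fixed"`).
#' @param classifierThreshold decision threshold in (0, 1).
#' @param seed integer seed for seeded stages.
#' @return An [AnalysisConfig-class].
#' @examples
#' cfg <- AnalysisConfig()
#' diskRadii(cfg)  # 6, 11, ..., 41 um
#' @export
AnalysisConfig <- function(diskInit = 6, diskIncrement = 5,
                           diskIterations = 8L, binarizeMethod = "otsu",
                           binarizeThreshold = NA_real_,
                           minCandidateArea = 10, patchDilation = 4,
                           patchSize = 32L, gapTolerance = 0L,
                           alphaPolicy = "auto", alphaFixed = NA_real_,
                           classifierThreshold = 0.5, seed = 1L) {
  new("AnalysisConfig", diskInit = as.numeric(diskInit),
      diskIncrement = as.numeric(diskIncrement),
      diskIterations = as.integer(diskIterations),
      binarizeMethod = binarizeMethod,
      binarizeThreshold = as.numeric(binarizeThreshold),
      minCandidateArea = as.numeric(minCandidateArea),
      patchDilation = as.numeric(patchDilation),
      patchSize = as.integer(patchSize),
      gapTolerance = as.integer(gapTolerance), alphaPolicy = alphaPolicy,
      alphaFixed = as.numeric(alphaFixed),
      classifierThreshold = as.numeric(classifierThreshold),
      seed = as.integer(seed))
}

#' Closing-disk radii of a configuration
#'
#' Radius at iteration `i` (0-based) is `diskInit + i * diskIncrement`.
#'
#' @param config an [AnalysisConfig-class].
#' @return numeric vector of radii, um, one per iteration.
#' @export
diskRadii <- function(config) {
  config@diskInit + (seq_len(config@diskIterations) - 1) * config@diskIncrement
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat("  closing schedule:", paste(diskRadii(object), collapse = ", "),
      "um (", object@diskIterations, "iterations )\n")
  cat("  binarization:", object@binarizeMethod,
      if (object@binarizeMethod == "fixed")
        paste("@", object@binarizeThreshold) else "", "\n")
  cat("  min candidate area:", object@minCandidateArea, "px^2;",
      "patch:", object@patchSize, "px, dilation",
      object@patchDilation, "um\n")
  cat("  gap tolerance:", object@gapTolerance, "slice(s); alpha:",
      if (object@alphaPolicy == "auto") "auto (critical)"
      else paste(object@alphaFixed, "um"), "\n")
})

#' Read an AnalysisConfig from a YAML file
#'
#' Keys mirror the arguments of [AnalysisConfig()]; missing keys keep their
#' defaults, and `overrides` (e.g. parsed CLI flags) take precedence over
#' the file.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list of values overriding the file.
#' @return An [AnalysisConfig-class].
#' @export
readAnalysisConfig <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("invalid config file")
  }
  vals <- modifyList(vals, overrides)
  known <- names(formals(AnalysisConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(AnalysisConfig, vals)
}

#' Write an AnalysisConfig to YAML
#'
#' @param config an [AnalysisConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnalysisConfig <- function(config, path) {
  vals <- list(diskInit = config@diskInit,
               diskIncrement = config@diskIncrement,
               diskIterations = config@diskIterations,
               binarizeMethod = config@binarizeMethod,
               binarizeThreshold = config@binarizeThreshold,
               minCandidateArea = config@minCandidateArea,
               patchDilation = config@patchDilation,
               patchSize = config@patchSize,
               gapTolerance = config@gapTolerance,
               alphaPolicy = config@alphaPolicy,
               alphaFixed = config@alphaFixed,
               classifierThreshold = config@classifierThreshold,
               seed = config@seed)
  yaml::write_yaml(vals, path)
  invisible(path)
}
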