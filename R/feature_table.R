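# FeatureTable: SummarizedExperiment wrapper for the samples x features
# profiling currency, plus CSV I/O (features + a `group` column).

#' Construct a FeatureTable
#'
#' @param x numeric matrix, samples in rows, features in columns (column
#'   names become feature names; row names become sample ids).
#' @param group group (dose-level) label per sample.
#' @param sampleIds optional sample identifiers (default: row names of `x`,
#'   else `s1, s2, ...`).
#' @return A [FeatureTable-class].
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(NULL, paste0("f", 1:4)))
#' ft <- FeatureTable(m, group = rep(c("ctrl", "high"), c(3, 2)))
#' dim(featureMatrix(ft))
#' @export
FeatureTable <- function(x, group, sampleIds = NULL) {
  x <- as.matrix(x)
  if (length(group) != nrow(x))
    stop("need one group label per sample (row)")
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("feat_%03d", seq_len(ncol(x)))
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(x))) rownames(x)
                 else sprintf("s%03d", seq_len(nrow(x)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(x)),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = sampleIds))
  new("FeatureTable", se)
}

#' @describeIn FeatureTable the samples x features numeric matrix.
#' @param x a `FeatureTable`.
#' @export
setMethod("featureMatrix", "FeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @describeIn FeatureTable group label per sample (character).
#' @export
setMethod("groupLabels", "FeatureTable", function(x)
  SummarizedExperiment::colData(x)$group)

#' @describeIn FeatureTable replace the group labels.
#' @param value replacement labels, one per sample.
#' @export
setMethod("groupLabels<-", "FeatureTable", function(x, value) {
  if (length(value) != ncol(x)) stop("need one label per sample")
  SummarizedExperiment::colData(x)$group <- as.character(value)
  validObject(x)
  x
})

setMethod("show", "FeatureTable", function(object) {
  g <- table(groupLabels(object))
  cat("FeatureTable:", ncol(object), "samples x", nrow(object),
      "features\n  groups:",
      paste(sprintf("%s (%d)", names(g), g), collapse = ", "), "\n")
})

#' Read a feature table from CSV
#'
#' Expects one row per sample, numeric feature columns, a `group` column,
#' and optionally a `sample` column of identifiers.
#'
#' @param path CSV path.
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!"group" %in% names(df)) stop("feature CSV needs a 'group' column")
  ids <- if ("sample" %in% names(df)) as.character(df$sample) else NULL
  feats <- df[, setdiff(names(df), c("group", "sample")), drop = FALSE]
  FeatureTable(as.matrix(feats), group = df$group, sampleIds = ids)
}

#' Write a feature table to CSV
#'
#' @param table a [FeatureTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  m <- featureMatrix(table)
  df <- data.frame(sample = colnames(SummarizedExperiment::assay(table)),
                   group = groupLabels(table), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
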