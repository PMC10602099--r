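# Per-microtissue result container and JSON/CSV serialization.

#' Construct a MicrotissueResult
#'
#' @param id microtissue identifier.
#' @param volumes per-lumen volumes, um^3.
#' @param surfaceAreas per-lumen surface areas, um^2 (defaults to `NA` per
#'   lumen when unknown).
#' @return A [MicrotissueResult-class]; `lumenCount` and `totalVolume` are
#'   derived (`totalVolume = sum(volumes)`).
#' @examples
#' MicrotissueResult("mt1", volumes = c(100, 50))
#' @export
MicrotissueResult <- function(id, volumes = numeric(0),
                              surfaceAreas = rep(NA_real_, length(volumes))) {
  new("MicrotissueResult", id = as.character(id),
      lumenCount = length(volumes), volumes = as.numeric(volumes),
      surfaceAreas = as.numeric(surfaceAreas),
      totalVolume = sum(volumes))
}

#' @describeIn MicrotissueResult number of lumens.
#' @param x a `MicrotissueResult`.
#' @export
setMethod("lumenCount", "MicrotissueResult", function(x) x@lumenCount)

#' @describeIn MicrotissueResult per-lumen volumes, um^3.
#' @export
setMethod("lumenVolume", "MicrotissueResult", function(x) x@volumes)

#' @describeIn MicrotissueResult total luminal volume, um^3.
#' @export
setMethod("totalVolume", "MicrotissueResult", function(x) x@totalVolume)

#' @describeIn MicrotissueResult per-lumen surface areas, um^2.
#' @export
setMethod("surfaceArea", "MicrotissueResult", function(x) x@surfaceAreas)

setMethod("show", "MicrotissueResult", function(object) {
  cat("MicrotissueResult", object@id, ":", object@lumenCount, "lumen(s),",
      "total volume", signif(object@totalVolume, 6), "um^3\n")
})

#' Write microtissue results to JSON
#'
#' One object per microtissue with `id`, `lumen_count`, `volumes_um3`,
#' `surface_um2` and `total_volume_um3`. Values are written at full double
#' precision so [readResults()] reproduces them exactly.
#'
#' @param results list of [MicrotissueResult-class] (possibly empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
  recs <- lapply(results, function(r) {
    stopifnot(is(r, "MicrotissueResult"))
    list(id = r@id, lumen_count = r@lumenCount,
         volumes_um3 = as.list(r@volumes),
         surface_um2 = as.list(r@surfaceAreas),
         total_volume_um3 = r@totalVolume)
  })
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"), con)
  invisible(path)
}

#' Read microtissue results from JSON
#'
#' @param path a file written by [writeResults()].
#' @return list of [MicrotissueResult-class].
#' @export
readResults <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    vols <- as.numeric(unlist(r$volumes_um3))
    surf <- vapply(r$surface_um2, function(s)
      if (is.null(s)) NA_real_ else as.numeric(s), numeric(1))
    if (length(vols) == 0) surf <- numeric(0)
    MicrotissueResult(r$id, volumes = vols, surfaceAreas = surf)
  })
}

#' Export results as a long-format CSV
#'
#' One row per lumen (`microtissue_id, lumen, volume_um3, surface_um2`),
#' the layout violin-plot tooling expects; microtissues without lumens
#' contribute a single row with zero volume and `lumen = 0`.
#'
#' @param results list of [MicrotissueResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeResultsCsv <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    if (r@lumenCount == 0)
      return(data.frame(microtissue_id = r@id, lumen = 0L,
                        volume_um3 = 0, surface_um2 = NA_real_))
    data.frame(microtissue_id = r@id, lumen = seq_len(r@lumenCount),
               volume_um3 = r@volumes, surface_um2 = r@surfaceAreas)
  }))
  if (is.null(rows))
    rows <- data.frame(microtissue_id = character(0), lumen = integer(0),
                       volume_um3 = numeric(0), surface_um2 = numeric(0))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
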