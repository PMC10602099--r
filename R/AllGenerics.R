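# Generics for the accessor surface. Slot access from user code should go
# through these.

#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("getSlice", function(x, z, channel) standardGeneric("getSlice"))
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @export
setGeneric("groupLabels<-", function(x, value) standardGeneric("groupLabels<-"))
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @export
setGeneric("vipScores", function(x) standardGeneric("vipScores"))
#' @export
setGeneric("lumenVolume", function(x) standardGeneric("lumenVolume"))
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))
#' @export
setGeneric("lumenCount", function(x) standardGeneric("lumenCount"))
#' @export
setGeneric("totalVolume", function(x) standardGeneric("totalVolume"))
#' @export
setGeneric("classifyCandidates", function(model, patches, ...)
  standardGeneric("classifyCandidates"))
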