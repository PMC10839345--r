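#' @import methods
#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @export
setGeneric("asvIDs", function(object) standardGeneric("asvIDs"))

#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @export
setGeneric("nASVs", function(object) standardGeneric("nASVs"))

#' @export
setGeneric("dnaCounts", function(object) standardGeneric("dnaCounts"))

#' @export
setGeneric("rnaCounts", function(object) standardGeneric("rnaCounts"))

#' @export
setGeneric("samplePairs", function(object) standardGeneric("samplePairs"))

#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @export
setGeneric("ratios", function(object) standardGeneric("ratios"))

#' @export
setGeneric("isAbsent", function(object) standardGeneric("isAbsent"))

#' @export
setGeneric("activityStates", function(object) standardGeneric("activityStates"))

#' @export
setGeneric("activityThreshold", function(object) standardGeneric("activityThreshold"))

#' @export
setGeneric("shiftCodes", function(object) standardGeneric("shiftCodes"))
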