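#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @export
setGeneric("fitTable", function(x) standardGeneric("fitTable"))

#' @export
setGeneric("smoothedTrajectories", function(x) standardGeneric("smoothedTrajectories"))

#' @export
setGeneric("ageGrid", function(x) standardGeneric("ageGrid"))

#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @export
setGeneric("inclinations", function(x) standardGeneric("inclinations"))

#' @export
setGeneric("positionAge", function(x) standardGeneric("positionAge"))

#' @export
setGeneric("positionDecade", function(x) standardGeneric("positionDecade"))

#' @export
setGeneric("sampleCounts", function(x) standardGeneric("sampleCounts"))

#' @export
setGeneric("sampleWeights", function(x) standardGeneric("sampleWeights"))
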