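#' @rdname intervalCount
#' @export
setGeneric("intervalCount", function(x, ...) standardGeneric("intervalCount"))

#' @rdname coveredBases
#' @export
setGeneric("coveredBases", function(x, ...) standardGeneric("coveredBases"))

#' @rdname boundaryCount
#' @export
setGeneric("boundaryCount", function(x, ...) standardGeneric("boundaryCount"))

#' @rdname contextLabels
#' @export
setGeneric("contextLabels", function(x) standardGeneric("contextLabels"))

#' @rdname transitionMatrices
#' @export
setGeneric("transitionMatrices", function(x) standardGeneric("transitionMatrices"))

#' @rdname transitionMatrices
#' @export
setGeneric("trainingCounts", function(x) standardGeneric("trainingCounts"))

#' @rdname pmfMean
#' @export
setGeneric("pmfMean", function(x) standardGeneric("pmfMean"))

#' @rdname pmfMean
#' @export
setGeneric("pmfVariance", function(x) standardGeneric("pmfVariance"))

#' @rdname resultTable
#' @export
setGeneric("resultTable", function(x, ...) standardGeneric("resultTable"))
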