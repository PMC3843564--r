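#' @rdname ConnectivityPattern-class
#' @param x,object a \code{ConnectivityPattern} (or other ncatools object
#'   for shared generics).
#' @export
setGeneric("tfIds", function(x) standardGeneric("tfIds"))

#' @rdname ConnectivityPattern-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ConnectivityPattern-class
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))

#' @rdname ConnectivityPattern-class
#' @export
setGeneric("directionKnown", function(x) standardGeneric("directionKnown"))

#' @rdname ConnectivityPattern-class
#' @export
setGeneric("regulonSizes", function(x) standardGeneric("regulonSizes"))

#' @rdname ConnectivityPattern-class
#' @export
setGeneric("inDegrees", function(x) standardGeneric("inDegrees"))

#' @rdname ExpressionRatioSet-class
#' @param x an \code{ExpressionRatioSet}.
#' @export
setGeneric("ratioMatrices", function(x) standardGeneric("ratioMatrices"))

#' @rdname ExpressionRatioSet-class
#' @export
setGeneric("conditionIds", function(x) standardGeneric("conditionIds"))

#' @rdname ExpressionRatioSet-class
#' @export
setGeneric("logRatios", function(x) standardGeneric("logRatios"))

#' @rdname ExpressionRatioSet-class
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname ExpressionRatioSet-class
#' @export
setGeneric("meanLogRatios", function(x) standardGeneric("meanLogRatios"))

#' @rdname ComplianceReport-class
#' @param x a \code{ComplianceReport}.
#' @export
setGeneric("isCompliant", function(x) standardGeneric("isCompliant"))

#' @rdname DecompositionResult-class
#' @param x a \code{DecompositionResult} or \code{AggregateResult}.
#' @export
setGeneric("csMatrix", function(x) standardGeneric("csMatrix"))

#' @rdname DecompositionResult-class
#' @export
setGeneric("logTfa", function(x) standardGeneric("logTfa"))

#' @rdname DecompositionResult-class
#' @export
setGeneric("objective", function(x) standardGeneric("objective"))

#' @rdname DecompositionResult-class
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
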