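#' @include dtiBoost-package.R
NULL

#' Accessor generics
#'
#' Small family of accessors for the core S4 classes. Slot access via `@`
#' is considered internal; use these instead.
#'
#' @param x an object of one of the dtiBoost S4 classes.
#' @return The corresponding slot value; see the class documentation.
#' @name accessors
#' @aliases proteinId drugId proteinSequence pssmScores ssLabels asaValues
#'   torsionAngles structProbs fpBits networkDrugs networkTargets
#'   networkEdges pairLabels pairKeys featureMatrix positiveCount
#'   negativeCount stageWeights stageErrors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname accessors
#' @export
setGeneric("drugId", function(x) standardGeneric("drugId"))

#' @rdname accessors
#' @export
setGeneric("proteinSequence", function(x) standardGeneric("proteinSequence"))

#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))

#' @rdname accessors
#' @export
setGeneric("ssLabels", function(x) standardGeneric("ssLabels"))

#' @rdname accessors
#' @export
setGeneric("asaValues", function(x) standardGeneric("asaValues"))

#' @rdname accessors
#' @export
setGeneric("torsionAngles", function(x) standardGeneric("torsionAngles"))

#' @rdname accessors
#' @export
setGeneric("structProbs", function(x) standardGeneric("structProbs"))

#' @rdname accessors
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

#' @rdname accessors
#' @export
setGeneric("networkDrugs", function(x) standardGeneric("networkDrugs"))

#' @rdname accessors
#' @export
setGeneric("networkTargets", function(x) standardGeneric("networkTargets"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname accessors
#' @export
setGeneric("pairKeys", function(x) standardGeneric("pairKeys"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("positiveCount", function(x) standardGeneric("positiveCount"))

#' @rdname accessors
#' @export
setGeneric("negativeCount", function(x) standardGeneric("negativeCount"))

#' @rdname accessors
#' @export
setGeneric("stageWeights", function(x) standardGeneric("stageWeights"))

#' @rdname accessors
#' @export
setGeneric("stageErrors", function(x) standardGeneric("stageErrors"))
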