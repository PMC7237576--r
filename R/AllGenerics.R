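#' @include AllClasses.R
NULL

#' Accessors for stagenet classes
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param x a stagenet object.
#' @param ... unused.
#' @return see individual methods.
#' @name stagenet-accessors
NULL

#' @rdname stagenet-accessors
#' @export
setGeneric("exprMatrix", function(x, ...) standardGeneric("exprMatrix"))

#' @rdname stagenet-accessors
#' @export
setGeneric("sampleStage", function(x, ...) standardGeneric("sampleStage"))

#' @rdname stagenet-accessors
#' @export
setGeneric("clinicalData", function(x, ...) standardGeneric("clinicalData"))

#' @rdname stagenet-accessors
#' @export
setGeneric("cohortTruth", function(x, ...) standardGeneric("cohortTruth"))

#' @rdname stagenet-accessors
#' @export
setGeneric("stageLabel", function(x, ...) standardGeneric("stageLabel"))

#' @rdname stagenet-accessors
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))

#' @rdname stagenet-accessors
#' @export
setGeneric("tfNodes", function(x, ...) standardGeneric("tfNodes"))

#' @rdname stagenet-accessors
#' @export
setGeneric("lncNodes", function(x, ...) standardGeneric("lncNodes"))

#' @rdname stagenet-accessors
#' @export
setGeneric("activityMatrix", function(x, ...) standardGeneric("activityMatrix"))

#' @rdname stagenet-accessors
#' @export
setGeneric("rawCorrelations", function(x, ...) standardGeneric("rawCorrelations"))

#' @rdname stagenet-accessors
#' @export
setGeneric("specificity", function(x, ...) standardGeneric("specificity"))

#' @rdname stagenet-accessors
#' @export
setGeneric("activityGroups", function(x, ...) standardGeneric("activityGroups"))

#' @rdname stagenet-accessors
#' @export
setGeneric("cliques", function(x, ...) standardGeneric("cliques"))

#' @rdname stagenet-accessors
#' @export
setGeneric("cliqueStats", function(x, ...) standardGeneric("cliqueStats"))

#' @rdname stagenet-accessors
#' @export
setGeneric("riskCoefficients", function(x, ...) standardGeneric("riskCoefficients"))

#' @rdname stagenet-accessors
#' @export
setGeneric("riskCutoff", function(x, ...) standardGeneric("riskCutoff"))
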