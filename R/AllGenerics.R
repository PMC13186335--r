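#' @rdname HervReference-accessors
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))

#' @rdname HervReference-accessors
#' @export
setGeneric("locusRanges", function(x) standardGeneric("locusRanges"))

#' @rdname HervReference-accessors
#' @export
setGeneric("locusSequences", function(x) standardGeneric("locusSequences"))

#' @rdname HervReference-accessors
#' @export
setGeneric("locusLengths", function(x) standardGeneric("locusLengths"))

#' @rdname WindowCoverage-accessors
#' @export
setGeneric("windowDepths", function(x) standardGeneric("windowDepths"))

#' @rdname CohortMatrix-accessors
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname CohortMatrix-accessors
#' @export
setGeneric("detectionCount", function(x) standardGeneric("detectionCount"))

#' @rdname CohortMatrix-accessors
#' @export
setGeneric("presenceStatus", function(x) standardGeneric("presenceStatus"))
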