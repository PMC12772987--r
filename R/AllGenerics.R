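#' @rdname accessors
#' @param x an apneaflow object
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("flowSamples", function(x) standardGeneric("flowSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))

#' @rdname accessors
#' @export
setGeneric("sleepTime", function(x) standardGeneric("sleepTime"))

#' @rdname accessors
#' @export
setGeneric("trueAhi", function(x) standardGeneric("trueAhi"))

#' @rdname accessors
#' @export
setGeneric("segmentMatrix", function(x) standardGeneric("segmentMatrix"))

#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname accessors
#' @export
setGeneric("segmentStarts", function(x) standardGeneric("segmentStarts"))

#' @rdname accessors
#' @export
setGeneric("segmentMinutes", function(x) standardGeneric("segmentMinutes"))

#' @rdname accessors
#' @export
setGeneric("architecture", function(x) standardGeneric("architecture"))

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
#' @export
setGeneric("bestEpoch", function(x) standardGeneric("bestEpoch"))

#' @rdname accessors
#' @export
setGeneric("ahi", function(x) standardGeneric("ahi"))

#' @rdname accessors
#' @export
setGeneric("severity", function(x) standardGeneric("severity"))

#' @rdname accessors
#' @export
setGeneric("meanSegmentPred", function(x) standardGeneric("meanSegmentPred"))

#' @rdname accessors
#' @export
setGeneric("attributionValues", function(x) standardGeneric("attributionValues"))

#' @rdname accessors
#' @export
setGeneric("attributionKind", function(x) standardGeneric("attributionKind"))
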