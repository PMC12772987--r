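#' Accessors for apneaflow objects
#'
#' Slot accessors for the S4 containers: recordings, segment sets, models,
#' estimates, and attribution maps.
#'
#' @name accessors
NULL

#' @rdname accessors
setMethod("subjectId", "AirflowRecord", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "SegmentSet", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "AHIEstimate", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "AttributionMap", function(x) x@subjectId)

#' @rdname accessors
setMethod("annotations", "AirflowRecord", function(x) x@annotations)
#' @rdname accessors
setMethod("flowSamples", "AirflowRecord", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "AirflowRecord", function(x) x@fs)
#' @rdname accessors
setMethod("recordDuration", "AirflowRecord", function(x) x@duration)
#' @rdname accessors
setMethod("sleepTime", "AirflowRecord", function(x) x@sleepTime)
#' @rdname accessors
setMethod("trueAhi", "AirflowRecord", function(x) x@trueAhi)

#' @rdname accessors
setMethod("segmentMatrix", "SegmentSet", function(x) x@segments)
#' @rdname accessors
setMethod("segmentLabels", "SegmentSet", function(x) x@labels)
#' @rdname accessors
setMethod("segmentStarts", "SegmentSet", function(x) x@startTimes)
#' @rdname accessors
setMethod("segmentMinutes", "SegmentSet", function(x) x@segmentMinutes)

#' @rdname accessors
setMethod("architecture", "TrainedModel", function(x) x@config)
#' @rdname accessors
setMethod("trainingHistory", "TrainedModel", function(x) x@history)
#' @rdname accessors
setMethod("bestEpoch", "TrainedModel", function(x) x@bestEpoch)

#' @rdname accessors
setMethod("ahi", "AHIEstimate", function(x) x@ahi)
#' @rdname accessors
setMethod("severity", "AHIEstimate", function(x) x@severity)
#' @rdname accessors
setMethod("meanSegmentPred", "AHIEstimate", function(x) x@meanSegmentPred)

#' @rdname accessors
setMethod("attributionValues", "AttributionMap", function(x) x@values)
#' @rdname accessors
setMethod("attributionKind", "AttributionMap", function(x) x@kind)

setMethod("show", "SimConfig", function(object) {
    wf <- paste(format(object@wakeFraction), collapse = "-")
    cat("SimConfig:", object@duration, "s at", object@fsOut, "Hz |",
        object@targetEventRate, "events/h sleep (apnea fraction",
        object@apneaFraction, ") | wake", wf, "| seed", object@seed, "\n")
})

setMethod("show", "AirflowRecord", function(object) {
    nResp <- sum(object@annotations$kind %in% c("apnea", "hypopnea"))
    cat("AirflowRecord ", object@subjectId, "\n",
        sprintf("  %.0f s at %g Hz (%d samples), sleep time %.0f s\n",
                object@duration, object@fs, length(object@samples),
                object@sleepTime),
        sprintf("  %d respiratory events (%d annotations), true AHI %s e/h\n",
                nResp, nrow(object@annotations),
                ifelse(is.na(object@trueAhi), "unknown",
                       format(round(object@trueAhi, 2)))), sep = "")
})

setMethod("show", "SegmentSet", function(object) {
    cat("SegmentSet ", object@subjectId, "\n",
        sprintf("  %d segments of %d min (%d samples at 4 Hz)\n",
                nrow(object@segments), object@segmentMinutes,
                ncol(object@segments)),
        sprintf("  event-count labels: %s\n",
                paste(object@labels, collapse = " ")), sep = "")
})

setMethod("show", "ModelConfig", function(object) {
    cat(sprintf(
        "ModelConfig: %d conv block(s) x %d filters (kernel %d, pool %d, dropout %g), input length %d\n",
        object@nBlocks, object@nFilters, object@kernel, object@pool,
        object@rDrop, object@inputLength))
    cat(sprintf("  trainable parameters: %d\n", countParams(object)))
})

setMethod("show", "TrainedModel", function(object) {
    show(object@config)
    if (nrow(object@history) == 0L) {
        cat("  untrained\n")
    } else {
        cat(sprintf("  trained %d epoch(s); best epoch %d (val loss %.4f)\n",
                    nrow(object@history), object@bestEpoch,
                    object@history$valLoss[object@bestEpoch]))
    }
})

setMethod("show", "CorrectionModel", function(object) {
    cat(sprintf("CorrectionModel: AHI = %.4f x meanPred + %.4f (fit on %d subjects)\n",
                object@slope, object@intercept, object@fitN))
})

setMethod("show", "AHIEstimate", function(object) {
    cat(sprintf("AHIEstimate %s: mean segment prediction %.3f -> AHI %.2f e/h (%s)\n",
                object@subjectId, object@meanSegmentPred, object@ahi,
                object@severity))
})

setMethod("show", "AttributionMap", function(object) {
    cat(sprintf("AttributionMap (%s) %s segment %d: %d samples, range [%.3g, %.3g]\n",
                object@kind, object@subjectId, object@segmentIndex,
                length(object@values), min(object@values), max(object@values)))
})

setMethod("show", "DiagnosticReport", function(object) {
    cat(sprintf("DiagnosticReport on %d subjects\n", object@n))
    cat(sprintf("  ICC %.3f | RMSE %.3f e/h | 4-class kappa %.3f | Acc4 %.2f%%\n",
                object@icc, object@rmse, object@kappa, object@acc4))
    ba <- object@blandAltman
    cat(sprintf("  Bland-Altman: mean diff %.3f, LoA [%.3f, %.3f], %.1f%% within\n",
                ba$meanDiff, ba$loaLow, ba$loaHigh, 100 * ba$withinFraction))
    for (co in names(object@cutoffs)) {
        m <- object@cutoffs[[co]]
        cat(sprintf("  cutoff %s e/h: Se %.1f%% Sp %.1f%% Acc %.1f%% PPV %.1f%% NPV %.1f%% LR+ %.2f LR- %.2f\n",
                    co, m$Se, m$Sp, m$Acc, m$PPV, m$NPV, m$LRpos, m$LRneg))
    }
    cat("  confusion (rows actual / cols predicted):\n")
    print(object@confusion)
})
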