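#' @import methods
NULL

## Canonical ordering of the four OSA severity classes (events/hour of sleep:
## <1, [1,5), [5,10), >=10).
.SEVERITY_LEVELS <- c("no_osa", "mild", "moderate", "severe")

## Annotation kinds carried by an AirflowRecord. Only apnea/hypopnea count as
## respiratory events; artifact and wake are contextual.
.ANNOTATION_KINDS <- c("apnea", "hypopnea", "artifact", "wake")

.validAnnotations <- function(ann, duration = NULL) {
    req <- c("onset_sec", "duration_sec", "kind")
    if (!is.data.frame(ann)) {
        return("'annotations' must be a data.frame")
    }
    if (!all(req %in% names(ann))) {
        return(sprintf("annotations need columns %s", paste(req, collapse = ", ")))
    }
    if (nrow(ann) == 0L) {
        return(TRUE)
    }
    if (!all(ann$kind %in% .ANNOTATION_KINDS)) {
        return(sprintf("unknown annotation kind(s): %s",
                       paste(setdiff(unique(ann$kind), .ANNOTATION_KINDS),
                             collapse = ", ")))
    }
    if (any(ann$onset_sec < 0) || any(ann$duration_sec <= 0)) {
        return("annotation onsets must be >= 0 and durations > 0")
    }
    if (!is.null(duration) &&
        any(ann$onset_sec + ann$duration_sec > duration + 1e-6)) {
        return("annotation extends beyond the end of the recording")
    }
    resp <- ann[ann$kind %in% c("apnea", "hypopnea"), , drop = FALSE]
    if (nrow(resp) > 1L) {
        o <- order(resp$onset_sec)
        s <- resp$onset_sec[o]
        e <- s + resp$duration_sec[o]
        if (any(s[-1L] < e[-length(e)] - 1e-9)) {
            return("respiratory events overlap")
        }
    }
    TRUE
}

#' Simulation settings for synthetic pediatric airflow
#'
#' Collects every tunable of the airflow simulator: output sampling rate,
#' recording length, breathing rate band, the target respiratory event rate
#' (events per hour of sleep, i.e. the target AHI), the apnea/hypopnea mix,
#' event durations, artifact rate, wake fraction, and noise scale.
#'
#' @slot fsOut output sampling rate in Hz
#' @slot duration recording length in seconds
#' @slot breathRateRange breaths per minute, length-2 interval
#' @slot targetEventRate respiratory events per hour of sleep
#' @slot apneaFraction proportion of events that are apneas (rest hypopneas)
#' @slot eventDurationRange event duration interval in seconds
#' @slot artifactRate artifacts per hour of recording
#' @slot wakeFraction proportion of the recording spent awake; scalar or a
#'   length-2 interval from which each record draws its own value
#' @slot noiseSd additive Gaussian noise SD relative to baseline amplitude
#' @slot seed integer seed; regeneration with the same seed is bit-identical
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        fsOut = "numeric", duration = "numeric",
        breathRateRange = "numeric", targetEventRate = "numeric",
        apneaFraction = "numeric", eventDurationRange = "numeric",
        artifactRate = "numeric", wakeFraction = "numeric",
        noiseSd = "numeric", seed = "integer"
    ),
    validity = function(object) {
        msg <- character()
        if (object@fsOut <= 0) msg <- c(msg, "fsOut must be > 0")
        if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
        br <- object@breathRateRange
        if (length(br) != 2L || any(br <= 0) || br[1L] > br[2L]) {
            msg <- c(msg, "breathRateRange must be a positive increasing pair")
        }
        wf <- object@wakeFraction
        if (any(wf < 0) || any(wf >= 1)) {
            msg <- c(msg, "wakeFraction must satisfy 0 <= wakeFraction < 1")
        }
        if (length(wf) == 2L && wf[1L] > wf[2L]) {
            msg <- c(msg, "wakeFraction range must be increasing")
        }
        ed <- object@eventDurationRange
        if (length(ed) != 2L || ed[1L] > ed[2L] || ed[1L] <= 0) {
            msg <- c(msg, "eventDurationRange must be a positive increasing pair")
        }
        ## an event must span at least two breath cycles at the slowest rate
        if (length(br) == 2L && length(ed) == 2L &&
            ed[1L] < 2 * 60 / br[1L] - 1e-9) {
            msg <- c(msg, sprintf(
                "event duration lower bound (%g s) shorter than two breath cycles at the slowest rate (%g s)",
                ed[1L], 2 * 60 / br[1L]))
        }
        if (object@targetEventRate < 0) msg <- c(msg, "targetEventRate must be >= 0")
        if (object@artifactRate < 0) msg <- c(msg, "artifactRate must be >= 0")
        if (object@apneaFraction < 0 || object@apneaFraction > 1) {
            msg <- c(msg, "apneaFraction must be in [0, 1]")
        }
        if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
        if (length(msg)) msg else TRUE
    }
)

#' An annotated single-channel airflow recording
#'
#' The central raw-data container: the airflow samples, their sampling rate,
#' the recording duration, the estimated total sleep time, event annotations
#' (apnea, hypopnea, artifact, wake) and, when known (simulated data), the
#' ground-truth AHI computed as 3600 x (#apneas + #hypopneas) / sleep time.
#'
#' @slot subjectId subject identifier
#' @slot samples numeric airflow series
#' @slot fs sampling rate in Hz
#' @slot duration recording duration in seconds
#' @slot sleepTime estimated total sleep time in seconds
#' @slot annotations data.frame with columns onset_sec, duration_sec, kind
#' @slot trueAhi ground-truth AHI in events/hour of sleep (NA when unknown)
#' @exportClass AirflowRecord
setClass("AirflowRecord",
    representation(
        subjectId = "character", samples = "numeric", fs = "numeric",
        duration = "numeric", sleepTime = "numeric",
        annotations = "data.frame", trueAhi = "numeric"
    ),
    validity = function(object) {
        msg <- character()
        if (length(object@samples) != round(object@duration * object@fs)) {
            msg <- c(msg, "length(samples) must equal round(duration * fs)")
        }
        if (object@sleepTime > object@duration + 1e-9) {
            msg <- c(msg, "sleepTime cannot exceed duration")
        }
        av <- .validAnnotations(object@annotations, object@duration)
        if (!isTRUE(av)) msg <- c(msg, av)
        if (isTRUE(av) && !is.na(object@trueAhi)) {
            nResp <- sum(object@annotations$kind %in% c("apnea", "hypopnea"))
            expect <- 3600 * nResp / object@sleepTime
            if (abs(expect - object@trueAhi) > 1e-6) {
                msg <- c(msg, sprintf(
                    "trueAhi (%g) inconsistent with annotations (%g)",
                    object@trueAhi, expect))
            }
        }
        if (length(msg)) msg else TRUE
    }
)

#' Standardized fixed-length airflow segments with event-count labels
#'
#' Rows are consecutive non-overlapping z-scored segments of the 4 Hz airflow
#' signal (5, 10, or 20 minutes: 1200, 2400, or 4800 samples); labels count
#' the apnea+hypopnea annotations whose onset falls inside each segment.
#'
#' @slot subjectId subject identifier
#' @slot segmentMinutes segment length in minutes (5, 10, or 20)
#' @slot segments numeric matrix, one z-scored segment per row
#' @slot labels integer per-segment respiratory event counts
#' @slot startTimes segment start times in seconds from record start
#' @exportClass SegmentSet
setClass("SegmentSet",
    representation(
        subjectId = "character", segmentMinutes = "integer",
        segments = "matrix", labels = "integer", startTimes = "numeric"
    ),
    validity = function(object) {
        msg <- character()
        L <- object@segmentMinutes * 60L * 4L
        if (ncol(object@segments) != L) {
            msg <- c(msg, sprintf("segments must have %d columns (got %d)",
                                  L, ncol(object@segments)))
        }
        n <- nrow(object@segments)
        if (length(object@labels) != n || length(object@startTimes) != n) {
            msg <- c(msg, "labels and startTimes must match nrow(segments)")
        }
        if (any(object@labels < 0L)) msg <- c(msg, "labels must be >= 0")
        if (n > 0L) {
            m <- rowMeans(object@segments)
            s <- apply(object@segments, 1L, stats::sd)
            zeroRow <- apply(object@segments == 0, 1L, all)
            bad <- !zeroRow & (abs(m) > 1e-6 | abs(s - 1) > 1e-6)
            if (any(bad)) {
                msg <- c(msg, "non-constant segment rows must be z-scored")
            }
        }
        if (length(msg)) msg else TRUE
    }
)

#' Convolutional network architecture hyperparameters
#'
#' Each of the \code{nBlocks} convolutional blocks is conv (\code{nFilters}
#' filters, odd \code{kernel}, stride 1, same padding) -> batch norm -> ReLU
#' -> max-pool(\code{pool}) -> dropout(\code{rDrop}); a flatten layer and a
#' single linear output unit produce the per-segment event-count estimate.
#' \code{nBlocks = 0} degenerates to a pure linear model on the raw segment
#' (useful as a baseline and for analytic attribution checks).
#'
#' @slot nBlocks number of convolutional blocks (>= 0)
#' @slot nFilters filters per convolution
#' @slot kernel kernel size (odd)
#' @slot stride convolution stride (fixed at 1)
#' @slot pool max-pool size/stride
#' @slot rDrop dropout rate in [0, 1)
#' @slot inputLength segment length in samples (1200, 2400, or 4800 at 4 Hz)
#' @exportClass ModelConfig
setClass("ModelConfig",
    representation(
        nBlocks = "integer", nFilters = "integer", kernel = "integer",
        stride = "integer", pool = "integer", rDrop = "numeric",
        inputLength = "integer"
    ),
    validity = function(object) {
        msg <- character()
        if (object@nBlocks < 0L) msg <- c(msg, "nBlocks must be >= 0")
        if (object@nFilters < 1L) msg <- c(msg, "nFilters must be >= 1")
        if (object@kernel %% 2L != 1L) msg <- c(msg, "kernel must be odd")
        if (object@stride != 1L) msg <- c(msg, "stride is fixed at 1")
        if (object@pool < 1L) msg <- c(msg, "pool must be >= 1")
        if (object@rDrop < 0 || object@rDrop >= 1) {
            msg <- c(msg, "rDrop must be in [0, 1)")
        }
        L <- object@inputLength
        for (b in seq_len(object@nBlocks)) L <- L %/% object@pool
        if (L < 1L) {
            msg <- c(msg, "inputLength collapses to zero after pooling; reduce nBlocks")
        }
        if (length(msg)) msg else TRUE
    }
)

#' Optimization settings for the event-count regressor
#'
#' Adam at initial learning rate \code{lr0}; the learning rate is divided by
#' \code{lrDecayFactor} after \code{lrPatience} epochs without improvement of
#' the validation loss, and training stops after \code{earlyStopPatience}
#' stagnant epochs or \code{maxEpochs}. The loss is the Huber loss with
#' threshold \code{huberDelta}.
#'
#' @slot lr0 initial learning rate
#' @slot batchSize minibatch size
#' @slot lrDecayFactor plateau decay divisor
#' @slot lrPatience epochs of stagnation before a decay
#' @slot earlyStopPatience epochs of stagnation before stopping
#' @slot huberDelta Huber loss threshold
#' @slot maxEpochs epoch cap
#' @slot seed integer seed for shuffling and dropout
#' @exportClass TrainConfig
setClass("TrainConfig",
    representation(
        lr0 = "numeric", batchSize = "integer", lrDecayFactor = "numeric",
        lrPatience = "integer", earlyStopPatience = "integer",
        huberDelta = "numeric", maxEpochs = "integer", seed = "integer"
    ),
    validity = function(object) {
        msg <- character()
        if (object@lr0 <= 0) msg <- c(msg, "lr0 must be > 0")
        if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
        if (object@lrDecayFactor <= 1) msg <- c(msg, "lrDecayFactor must be > 1")
        if (object@lrPatience < 1L || object@earlyStopPatience < 1L) {
            msg <- c(msg, "patiences must be >= 1")
        }
        if (object@huberDelta <= 0) msg <- c(msg, "huberDelta must be > 0")
        if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
        if (length(msg)) msg else TRUE
    }
)

#' A (possibly trained) convolutional event-count regressor
#'
#' Holds the architecture, the parameter store, the per-epoch training
#' history (train/validation loss and learning rate) and the index of the
#' epoch with the lowest validation loss, whose weights are the ones kept.
#'
#' @slot config a \linkS4class{ModelConfig}
#' @slot params parameter store (list of per-block weight arrays)
#' @slot history data.frame with columns epoch, trainLoss, valLoss, lr
#' @slot bestEpoch epoch with the lowest validation loss (NA before training)
#' @exportClass TrainedModel
setClass("TrainedModel",
    representation(
        config = "ModelConfig", params = "list",
        history = "data.frame", bestEpoch = "integer"
    ),
    validity = function(object) {
        if (nrow(object@history) > 0L && !is.na(object@bestEpoch)) {
            if (object@bestEpoch != which.min(object@history$valLoss)) {
                return("bestEpoch must index the minimum validation loss")
            }
        }
        TRUE
    }
)

#' Linear AHI correction fitted on training subjects
#'
#' Ordinary least squares of the PSG-style reference AHI on the subject mean
#' per-segment prediction. The slope absorbs both the events-per-segment to
#' events-per-hour conversion (60 / segment minutes) and the inflation due to
#' total sleep time being shorter than total recording time.
#'
#' @slot slope regression slope
#' @slot intercept regression intercept
#' @slot fitN number of training subjects used in the fit
#' @exportClass CorrectionModel
setClass("CorrectionModel",
    representation(slope = "numeric", intercept = "numeric", fitN = "integer"),
    validity = function(object) {
        if (object@fitN < 2L) return("fitN must be >= 2")
        TRUE
    }
)

#' Subject-level AHI estimate
#'
#' @slot subjectId subject identifier
#' @slot meanSegmentPred mean per-segment predicted event count
#' @slot ahi corrected AHI estimate in events/hour (clamped at 0)
#' @slot severity one of no_osa, mild, moderate, severe
#' @exportClass AHIEstimate
setClass("AHIEstimate",
    representation(
        subjectId = "character", meanSegmentPred = "numeric",
        ahi = "numeric", severity = "character"
    ),
    validity = function(object) {
        msg <- character()
        if (object@ahi < 0) msg <- c(msg, "ahi must be >= 0")
        if (!object@severity %in% .SEVERITY_LEVELS) {
            msg <- c(msg, "unknown severity level")
        } else if (object@severity != .classifyOne(object@ahi)) {
            msg <- c(msg, "severity inconsistent with ahi")
        }
        if (length(msg)) msg else TRUE
    }
)

#' Per-sample attribution aligned to one input segment
#'
#' Grad-CAM maps live in [0, 1]; Deep-SHAP values are signed and satisfy the
#' completeness identity (they sum to the prediction minus the expected
#' background prediction).
#'
#' @slot subjectId subject identifier
#' @slot segmentIndex index of the explained segment within its SegmentSet
#' @slot values per-sample relevance, same length as the input segment
#' @slot kind "gradcam" or "shap"
#' @slot meta list: layers used (gradcam) or background size and completeness
#'   gap (shap)
#' @exportClass AttributionMap
setClass("AttributionMap",
    representation(
        subjectId = "character", segmentIndex = "integer",
        values = "numeric", kind = "character", meta = "list"
    ),
    validity = function(object) {
        msg <- character()
        if (!object@kind %in% c("gradcam", "shap")) {
            msg <- c(msg, "kind must be 'gradcam' or 'shap'")
        }
        if (any(!is.finite(object@values))) {
            msg <- c(msg, "attribution values must be finite")
        }
        if (object@kind == "gradcam" &&
            (any(object@values < -1e-12) || any(object@values > 1 + 1e-12))) {
            msg <- c(msg, "gradcam values must lie in [0, 1]")
        }
        if (length(msg)) msg else TRUE
    }
)

#' Agreement and diagnostic statistics for a cohort
#'
#' @slot cutoffs named list ("1", "5", "10") of binary diagnostics at each
#'   AHI cutoff: Se, Sp, Acc, PPV, NPV in percent, LR+ and LR- as ratios,
#'   plus a vector of flagged-undefined metric names
#' @slot kappa 4-class Cohen's kappa
#' @slot acc4 4-class accuracy in percent
#' @slot icc intraclass correlation (two-way, single-measure, absolute
#'   agreement)
#' @slot rmse root mean squared error in events/hour
#' @slot confusion 4x4 confusion matrix (rows actual, columns predicted)
#' @slot blandAltman list: meanDiff, loaLow, loaHigh, withinFraction,
#'   differences
#' @slot n number of subjects
#' @exportClass DiagnosticReport
setClass("DiagnosticReport",
    representation(
        cutoffs = "list", kappa = "numeric", acc4 = "numeric",
        icc = "numeric", rmse = "numeric", confusion = "matrix",
        blandAltman = "list", n = "integer"
    ),
    validity = function(object) {
        msg <- character()
        if (sum(object@confusion) != object@n) {
            msg <- c(msg, "confusion matrix entries must sum to n")
        }
        ba <- object@blandAltman
        if (!(ba$loaLow <= ba$meanDiff && ba$meanDiff <= ba$loaHigh)) {
            msg <- c(msg, "limits of agreement must bracket the mean difference")
        }
        if (length(msg)) msg else TRUE
    }
)
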