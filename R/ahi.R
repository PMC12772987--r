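## Subject-level AHI: average the per-segment predictions, then map the mean
## to events/hour with a linear correction fitted on training subjects only.
## The slope absorbs both the per-hour conversion (60 / segment minutes) and
## the inflation caused by scoring events against recording time while the
## reference AHI uses sleep time.

.classifyOne <- function(a) {
    if (a < 1) "no_osa" else if (a < 5) "mild" else if (a < 10) "moderate"
    else "severe"
}

#' Subject-level aggregate of per-segment predictions
#'
#' @param preds numeric vector of per-segment predicted event counts
#' @return their arithmetic mean
#' @export
aggregateSubject <- function(preds) {
    if (!length(preds)) stop("cannot aggregate an empty prediction list")
    mean(preds)
}

#' Fit the linear AHI correction
#'
#' Ordinary least squares of the reference AHI on the subject mean
#' per-segment prediction, fitted on training subjects only and applied
#' unchanged elsewhere (subject-wise separation).
#'
#' @param trainMeans per-subject mean segment predictions
#' @param trainActualAhi reference AHI per subject (events/hour)
#' @return a \linkS4class{CorrectionModel}
#' @export
fitCorrection <- function(trainMeans, trainActualAhi) {
    if (length(trainMeans) != length(trainActualAhi) ||
        length(trainMeans) < 2L) {
        stop("need equal-length vectors with at least 2 subjects")
    }
    if (stats::sd(trainMeans) < 1e-12) {
        stop("degenerate predictor: training means are all identical")
    }
    fit <- stats::lm(trainActualAhi ~ trainMeans)
    co <- stats::coef(fit)
    new("CorrectionModel", slope = unname(co[2L]), intercept = unname(co[1L]),
        fitN = length(trainMeans))
}

#' Classify OSA severity from an AHI
#'
#' Left-closed clinical cutoffs: no OSA for AHI < 1 e/h, mild for
#' 1 <= AHI < 5, moderate for 5 <= AHI < 10, severe for AHI >= 10.
#'
#' @param ahi AHI value(s), events/hour, >= 0
#' @return character vector of severity classes
#' @export
classifySeverity <- function(ahi) {
    if (any(ahi < 0)) stop("AHI must be non-negative")
    vapply(ahi, .classifyOne, character(1))
}

#' Corrected subject-level AHI estimate
#'
#' Applies the linear correction to the mean segment prediction and clamps
#' the result at zero (a negative AHI has no physical meaning).
#'
#' @param preds per-segment predicted counts for one subject
#' @param correction a \linkS4class{CorrectionModel}
#' @param subjectId subject identifier
#' @return an \linkS4class{AHIEstimate}
#' @export
estimateAhi <- function(preds, correction, subjectId = "subject") {
    stopifnot(is(correction, "CorrectionModel"))
    m <- aggregateSubject(preds)
    a <- max(0, correction@slope * m + correction@intercept)
    new("AHIEstimate", subjectId = subjectId, meanSegmentPred = m,
        ahi = a, severity = .classifyOne(a))
}

#' Train model and correction on a cohort
#'
#' Preprocesses the training and validation recordings, trains the
#' event-count regressor, and fits the AHI correction on the training
#' subjects (using their ground-truth AHI as the reference).
#'
#' @param trainRecords,valRecords lists of \linkS4class{AirflowRecord} with
#'   known \code{trueAhi}
#' @param config a \linkS4class{ModelConfig}
#' @param tc a \linkS4class{TrainConfig}
#' @param verbose print per-epoch progress
#' @return list with elements \code{model} (\linkS4class{TrainedModel}),
#'   \code{correction} (\linkS4class{CorrectionModel}), and
#'   \code{segmentMinutes}
#' @export
trainPipeline <- function(trainRecords, valRecords, config = presetConfig(),
                          tc = trainConfig(), verbose = FALSE) {
    segMin <- config@inputLength %/% 240L
    trainSets <- segmentCohort(trainRecords, segMin)
    valSets <- segmentCohort(valRecords, segMin)
    model <- buildModel(config, seed = tc@seed)
    model <- trainModel(model, trainSets, valSets, tc, verbose = verbose)
    means <- vapply(trainSets, function(s) {
        aggregateSubject(predictSegments(model, s))
    }, numeric(1))
    actual <- vapply(trainRecords, trueAhi, numeric(1))
    correction <- fitCorrection(means, actual)
    list(model = model, correction = correction, segmentMinutes = segMin)
}

#' Estimate AHI for a cohort of recordings
#'
#' @param model a trained \linkS4class{TrainedModel}
#' @param correction a \linkS4class{CorrectionModel}
#' @param records list of \linkS4class{AirflowRecord}
#' @param segmentMinutes segment length used by the model
#' @return data.frame: subjectId, meanSegmentPred, ahi, severity, and
#'   trueAhi where known
#' @export
estimateCohort <- function(model, correction, records, segmentMinutes = 10) {
    rows <- lapply(records, function(rec) {
        ss <- makeSegments(rec, segmentMinutes)
        est <- estimateAhi(predictSegments(model, ss), correction,
                           subjectId = subjectId(rec))
        data.frame(subjectId = subjectId(rec),
                   meanSegmentPred = meanSegmentPred(est),
                   ahi = ahi(est), severity = severity(est),
                   trueAhi = trueAhi(rec), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Hyperparameter selection by validation kappa
#'
#' Trains one model per (segmentMinutes, nBlocks, rDrop) configuration,
#' corrects and classifies the validation subjects, and returns the
#' configuration with the highest 4-class Cohen's kappa. Ties are broken in
#' favour of fewer blocks, then shorter segments. Configurations that fail
#' to train are recorded and excluded with a warning.
#'
#' @param grid data.frame with columns segmentMinutes, nBlocks, rDrop
#' @param trainRecords,valRecords cohorts with known \code{trueAhi}
#' @param nFilters filters per convolution for every candidate
#' @param tc a \linkS4class{TrainConfig}; its batch size is re-derived per
#'   segment length
#' @return list with \code{best} (one-row data.frame) and \code{table}
#'   (per-configuration validation kappa, NA for failures)
#' @export
selectConfiguration <- function(grid, trainRecords, valRecords,
                                nFilters = 16, tc = trainConfig()) {
    if (!nrow(grid)) stop("configuration grid is empty")
    kappas <- rep(NA_real_, nrow(grid))
    for (i in seq_len(nrow(grid))) {
        res <- tryCatch({
            cfg <- modelConfig(nBlocks = grid$nBlocks[i],
                               nFilters = nFilters,
                               segmentMinutes = grid$segmentMinutes[i],
                               rDrop = grid$rDrop[i])
            tci <- trainConfig(segmentMinutes = grid$segmentMinutes[i],
                               lr0 = tc@lr0, lrDecayFactor = tc@lrDecayFactor,
                               lrPatience = tc@lrPatience,
                               earlyStopPatience = tc@earlyStopPatience,
                               huberDelta = tc@huberDelta,
                               maxEpochs = tc@maxEpochs, seed = tc@seed)
            pipe <- trainPipeline(trainRecords, valRecords, cfg, tci)
            est <- estimateCohort(pipe$model, pipe$correction, valRecords,
                                  grid$segmentMinutes[i])
            cohenKappa(buildConfusion4(classifySeverity(est$trueAhi),
                                       est$severity))
        }, error = function(e) {
            warning("configuration ", i, " failed to train: ",
                    conditionMessage(e))
            NA_real_
        })
        kappas[i] <- res
    }
    tab <- cbind(grid, kappa = kappas)
    ok <- which(!is.na(kappas))
    if (!length(ok)) stop("every configuration failed to train")
    ord <- ok[order(-kappas[ok], grid$nBlocks[ok], grid$segmentMinutes[ok])]
    list(best = tab[ord[1L], , drop = FALSE], table = tab)
}
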