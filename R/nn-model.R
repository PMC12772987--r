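#' Architecture configuration for the event-count regressor
#'
#' @param nBlocks number of convolutional blocks (>= 0; 0 gives a pure
#'   linear model on the raw segment)
#' @param nFilters filters per convolution
#' @param segmentMinutes 5, 10, or 20; sets the input length (240 samples
#'   per minute at 4 Hz)
#' @param kernel odd kernel size
#' @param pool max-pool size/stride
#' @param rDrop dropout rate
#' @return a \linkS4class{ModelConfig}
#' @export
modelConfig <- function(nBlocks = 4, nFilters = 16, segmentMinutes = 10,
                        kernel = 5, pool = 2, rDrop = 0.1) {
    new("ModelConfig", nBlocks = as.integer(nBlocks),
        nFilters = as.integer(nFilters), kernel = as.integer(kernel),
        stride = 1L, pool = as.integer(pool), rDrop = rDrop,
        inputLength = as.integer(segmentMinutes) * 240L)
}

#' Preset architectures
#'
#' \code{"desk"} is the default working scale (4 blocks of 16 filters),
#' trainable on a single CPU in minutes. \code{"full"} is the full-scale
#' architecture (7 blocks of 256 filters) selected by validation kappa on
#' large clinical cohorts; it is provided for completeness and exercised
#' only in smoke tests.
#'
#' @param preset "desk" or "full"
#' @param segmentMinutes 5, 10, or 20
#' @param rDrop dropout rate (default 0.1, the selected value)
#' @return a \linkS4class{ModelConfig}
#' @export
presetConfig <- function(preset = c("desk", "full"), segmentMinutes = 10,
                         rDrop = 0.1) {
    preset <- match.arg(preset)
    if (preset == "desk") {
        modelConfig(nBlocks = 4, nFilters = 16,
                    segmentMinutes = segmentMinutes, rDrop = rDrop)
    } else {
        modelConfig(nBlocks = 7, nFilters = 256,
                    segmentMinutes = segmentMinutes, rDrop = rDrop)
    }
}

#' Number of trainable parameters
#'
#' Convolution (kernel x in-channels x filters + filters), batch-norm gain
#' and shift (2 x filters) per block, plus the linear head (flattened length
#' + 1). Running batch-norm statistics are not counted.
#'
#' @param config a \linkS4class{ModelConfig}
#' @return integer parameter count
#' @export
countParams <- function(config) {
    stopifnot(is(config, "ModelConfig"))
    total <- 0L
    Cin <- 1L
    L <- config@inputLength
    for (b in seq_len(config@nBlocks)) {
        Cout <- config@nFilters
        total <- total + config@kernel * Cin * Cout + Cout + 2L * Cout
        Cin <- Cout
        L <- L %/% config@pool
    }
    total + L * Cin + 1L
}

#' Build an untrained model
#'
#' Initializes conv weights He-normal, batch-norm to identity, and the linear
#' head to small random values, deterministically from the seed.
#'
#' @param config a \linkS4class{ModelConfig}
#' @param seed initialization seed
#' @return an untrained \linkS4class{TrainedModel}
#' @export
buildModel <- function(config, seed = 1L) {
    stopifnot(is(config, "ModelConfig"))
    validObject(config)
    new("TrainedModel", config = config,
        params = .nnInit(config, as.integer(seed)),
        history = data.frame(epoch = integer(0), trainLoss = numeric(0),
                             valLoss = numeric(0), lr = numeric(0)),
        bestEpoch = NA_integer_)
}

#' Huber loss
#'
#' \eqn{0.5 r^2} for \eqn{|r| \le \delta}, else
#' \eqn{\delta(|r| - \delta/2)}, with \eqn{r} the prediction error.
#' Vectorized; training minimizes its mean over the minibatch.
#'
#' @param prediction predicted value(s)
#' @param target target value(s)
#' @param delta threshold between the quadratic and linear regimes
#' @return elementwise non-negative loss
#' @export
huberLoss <- function(prediction, target, delta = 1) {
    if (any(!is.finite(prediction)) || any(!is.finite(target))) {
        stop("huberLoss requires finite inputs")
    }
    r <- prediction - target
    a <- abs(r)
    ifelse(a <= delta, 0.5 * r * r, delta * (a - delta / 2))
}

## d(huberLoss)/d(prediction)
.huberGrad <- function(r, delta = 1) {
    ifelse(abs(r) <= delta, r, delta * sign(r))
}

#' Predict per-segment event counts
#'
#' Inference mode: dropout inactive, batch normalization using running
#' statistics, so a segment's prediction does not depend on the batch it is
#' evaluated in. Predictions are unclamped (the subject-level correction
#' absorbs offsets; only the final AHI is clamped at zero).
#'
#' @param model a trained \linkS4class{TrainedModel}
#' @param segments a \linkS4class{SegmentSet} or a numeric matrix with one
#'   segment per row
#' @return numeric vector, one predicted count per segment
#' @export
predictSegments <- function(model, segments) {
    stopifnot(is(model, "TrainedModel"))
    X <- if (is(segments, "SegmentSet")) segmentMatrix(segments) else segments
    if (is.vector(X)) X <- matrix(X, nrow = 1L)
    if (ncol(X) != model@config@inputLength) {
        stop("segment length ", ncol(X), " does not match the model input length ",
             model@config@inputLength)
    }
    n <- nrow(X)
    preds <- numeric(n)
    chunk <- 256L
    cfg <- model@config
    for (s in seq(1L, n, by = chunk)) {
        e <- min(s + chunk - 1L, n)
        preds[s:e] <- as.vector(cppPredict(model@params,
                                           X[s:e, , drop = FALSE],
                                           cfg@kernel, cfg@pool))
    }
    preds
}
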