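#' Training configuration
#'
#' The optimizer protocol: Adam at an initial learning rate of 0.001, batch
#' size keyed to the segment length (256 for 5-min, 128 for 10-min, 64 for
#' 20-min segments), per-epoch random shuffling, learning-rate decay by a
#' factor of 2 after 10 epochs without validation-loss reduction, early
#' stopping after 30 stagnant epochs, Huber loss with delta 1. The epoch cap
#' defaults to 60 at working scale (full-scale runs would use 300; with few
#' minibatches per epoch the optimizer needs that many passes to reach its
#' validation plateau, and the patience rules end training when it does).
#'
#' @param segmentMinutes 5, 10, or 20 (sets the default batch size)
#' @param lr0 initial learning rate
#' @param batchSize minibatch size; default keyed by \code{segmentMinutes}
#' @param lrDecayFactor plateau decay divisor
#' @param lrPatience plateau patience (epochs)
#' @param earlyStopPatience early-stopping patience (epochs)
#' @param huberDelta Huber loss threshold
#' @param maxEpochs epoch cap
#' @param seed seed for shuffling and dropout
#' @return a \linkS4class{TrainConfig}
#' @export
trainConfig <- function(segmentMinutes = 10, lr0 = 0.001, batchSize = NULL,
                        lrDecayFactor = 2, lrPatience = 10,
                        earlyStopPatience = 30, huberDelta = 1,
                        maxEpochs = 60, seed = 1L) {
    if (is.null(batchSize)) {
        batchSize <- c(`5` = 256L, `10` = 128L, `20` = 64L)[
            as.character(segmentMinutes)]
        if (is.na(batchSize)) stop("segmentMinutes must be 5, 10, or 20")
    }
    new("TrainConfig", lr0 = lr0, batchSize = as.integer(batchSize),
        lrDecayFactor = lrDecayFactor, lrPatience = as.integer(lrPatience),
        earlyStopPatience = as.integer(earlyStopPatience),
        huberDelta = huberDelta, maxEpochs = as.integer(maxEpochs),
        seed = as.integer(seed))
}

## Stack one SegmentSet or a list of them into (X, y).
.stackSets <- function(sets) {
    if (is(sets, "SegmentSet")) sets <- list(sets)
    X <- do.call(rbind, lapply(sets, segmentMatrix))
    y <- unlist(lapply(sets, segmentLabels), use.names = FALSE)
    list(X = X, y = as.numeric(y))
}

.valLoss <- function(cfg, params, X, y, delta) {
    n <- nrow(X)
    tot <- 0
    for (s in seq(1L, n, by = 256L)) {
        e <- min(s + 255L, n)
        p <- as.vector(cppPredict(params, X[s:e, , drop = FALSE],
                                  cfg@kernel, cfg@pool))
        tot <- tot + sum(huberLoss(p, y[s:e], delta))
    }
    tot / n
}

## Recompute the batch-norm running statistics as the exact training-set
## moments under the current weights (chunk moments pooled by Welford-style
## combination; dropout off). Keeps validation-loss model selection free of
## the lag a small number of minibatches per epoch would otherwise leave in
## momentum-averaged statistics.
.refreshStats <- function(cfg, params, X, chunk = 256L) {
    if (cfg@nBlocks == 0L) {
        return(params)
    }
    n <- nrow(X)
    sumW <- 0
    m1 <- m2 <- vector("list", cfg@nBlocks)
    for (s in seq(1L, n, by = chunk)) {
        e <- min(s + chunk - 1L, n)
        st <- cppBatchStats(params, X[s:e, , drop = FALSE], cfg@kernel,
                            cfg@pool)
        w <- e - s + 1
        for (b in seq_len(cfg@nBlocks)) {
            mu <- st[[b]]$mean
            v <- st[[b]]$var
            if (is.null(m1[[b]])) {
                m1[[b]] <- w * mu
                m2[[b]] <- w * (v + mu^2)
            } else {
                m1[[b]] <- m1[[b]] + w * mu
                m2[[b]] <- m2[[b]] + w * (v + mu^2)
            }
        }
        sumW <- sumW + w
    }
    for (b in seq_len(cfg@nBlocks)) {
        mu <- m1[[b]] / sumW
        params$blocks[[b]]$rmean <- mu
        params$blocks[[b]]$rvar <- pmax(m2[[b]] / sumW - mu^2, 0)
    }
    params
}

#' Train the event-count regressor
#'
#' Minimizes the mean Huber loss over minibatches with Adam, shuffling every
#' epoch, decaying the learning rate on validation plateaus and stopping
#' early; the returned weights are those of the epoch with the lowest
#' validation loss. Fully reproducible given the seed (single-threaded BLAS
#' assumed for bitwise identity).
#'
#' @param model an untrained (or warm-start) \linkS4class{TrainedModel}
#' @param trainSets \linkS4class{SegmentSet} or list of them
#' @param valSets validation \linkS4class{SegmentSet} or list of them
#' @param tc a \linkS4class{TrainConfig}
#' @param verbose print one line per epoch
#' @return a trained \linkS4class{TrainedModel}
#' @export
trainModel <- function(model, trainSets, valSets, tc = trainConfig(),
                       verbose = FALSE) {
    stopifnot(is(model, "TrainedModel"), is(tc, "TrainConfig"))
    tr <- .stackSets(trainSets)
    va <- .stackSets(valSets)
    if (nrow(tr$X) == 0L || nrow(va$X) == 0L) {
        stop("training and validation sets must be non-empty")
    }
    cfg <- model@config
    if (ncol(tr$X) != cfg@inputLength) {
        stop("segment length does not match the model input length")
    }
    .withSeed(tc@seed, {
        params <- model@params
        state <- .adamInit(params)
        lr <- tc@lr0
        bestLoss <- Inf
        bestParams <- params
        bestEpoch <- NA_integer_
        lrWait <- 0L
        esWait <- 0L
        hist <- vector("list", tc@maxEpochs)
        n <- nrow(tr$X)
        for (epoch in seq_len(tc@maxEpochs)) {
            idx <- sample.int(n)
            lossSum <- 0
            starts <- seq(1L, n, by = tc@batchSize)
            for (bi in seq_along(starts)) {
                rows <- idx[starts[bi]:min(starts[bi] + tc@batchSize - 1L, n)]
                step <- cppTrainStep(params, tr$X[rows, , drop = FALSE],
                                     tr$y[rows], tc@huberDelta, cfg@kernel,
                                     cfg@pool, cfg@rDrop)
                if (!is.finite(step$loss)) {
                    stop(sprintf("non-finite training loss at epoch %d, batch %d",
                                 epoch, bi))
                }
                lossSum <- lossSum + step$loss
                st <- .adamStep(params, step$grads, state, lr)
                params <- st$params
                state <- st$state
                for (b in seq_len(cfg@nBlocks)) {
                    params$blocks[[b]]$rmean <-
                        0.9 * params$blocks[[b]]$rmean + 0.1 * step$stats[[b]]$mean
                    params$blocks[[b]]$rvar <-
                        0.9 * params$blocks[[b]]$rvar + 0.1 * step$stats[[b]]$var
                }
            }
            params <- .refreshStats(cfg, params, tr$X)
            trainLoss <- lossSum / n
            valLoss <- .valLoss(cfg, params, va$X, va$y, tc@huberDelta)
            if (!is.finite(valLoss)) {
                stop(sprintf("non-finite validation loss at epoch %d", epoch))
            }
            hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                        valLoss = valLoss, lr = lr)
            if (verbose) {
                message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                                epoch, trainLoss, valLoss, lr))
            }
            if (valLoss < bestLoss - 1e-12) {
                bestLoss <- valLoss
                bestParams <- params
                bestEpoch <- epoch
                lrWait <- 0L
                esWait <- 0L
            } else {
                lrWait <- lrWait + 1L
                esWait <- esWait + 1L
            }
            if (esWait >= tc@earlyStopPatience) break
            if (lrWait >= tc@lrPatience) {
                lr <- lr / tc@lrDecayFactor
                lrWait <- 0L
            }
        }
        history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
        rownames(history) <- NULL
        new("TrainedModel", config = cfg, params = bestParams,
            history = history, bestEpoch = bestEpoch)
    })
}
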