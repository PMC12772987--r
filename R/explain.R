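## Attribution for the scalar-output regressor.
##
## Grad-CAM: for each convolutional block, the gradient of the output with
## respect to the post-ReLU feature maps is averaged over time to weigh each
## map; the ReLU of the weighted sum is that block's heatmap. All block
## heatmaps are min-max normalized, linearly resized to the input length,
## and averaged into the final [0, 1] map.
##
## Deep-SHAP: DeepLIFT-style multipliers propagated from the output to the
## input for each background segment, averaged over the background set.
## Linear layers (conv, inference batch-norm, the head) pass multipliers
## exactly; ReLU uses the rescale rule; max-pooling is decomposed as
## max(a, b) = a + relu(b - a) so only linear ops and elementwise ReLUs
## remain and the completeness identity sum(phi) = f(x) - E_b f(b) holds to
## numerical tolerance by construction.

.minmaxNorm <- function(v) {
    rng <- max(v) - min(v)
    if (rng < 1e-12) return(numeric(length(v)))
    (v - min(v)) / rng
}

.resizeLinear <- function(v, L) {
    if (length(v) == L) return(v)
    if (length(v) == 1L) return(rep(v, L))
    stats::approx(seq_along(v), v, xout = seq(1, length(v), length.out = L))$y
}

## One inference forward + backward with per-block feature maps and their
## output gradients.
.gradCamPass <- function(model, segment) {
    cfg <- model@config
    if (cfg@nBlocks < 1L) {
        stop("Grad-CAM requires at least one convolutional block")
    }
    X <- matrix(segment, nrow = 1L)
    if (ncol(X) != cfg@inputLength) {
        stop("segment length does not match the model input length")
    }
    fwd <- .nnForward(cfg, model@params, X, training = FALSE, keep = TRUE)
    bwd <- .nnBackward(cfg, model@params, fwd, dpred = 1, training = FALSE,
                       tapGrads = TRUE)
    list(fwd = fwd, taps = bwd$taps)
}

#' Grad-CAM heatmap of one convolutional block
#'
#' Weights each post-ReLU feature map of the chosen block by the temporal
#' mean of the output gradient with respect to that map, sums, and applies a
#' ReLU; the result has the block's temporal resolution and is non-negative.
#'
#' @param model a trained \linkS4class{TrainedModel}
#' @param segment one z-scored input segment
#' @param blockIndex block to tap (1-based, <= number of blocks)
#' @return numeric non-negative heatmap of the block's temporal length
#' @export
gradCamLayer <- function(model, segment, blockIndex) {
    cfg <- model@config
    if (blockIndex < 1L || blockIndex > cfg@nBlocks) {
        stop("blockIndex must be in 1..", cfg@nBlocks)
    }
    pass <- .gradCamPass(model, segment)
    A <- pass$fwd$blocks[[blockIndex]]$relu
    g <- pass$taps[[blockIndex]]
    Tlen <- dim(A)[2L]
    Amat <- matrix(A, Tlen, dim(A)[3L])
    gmat <- matrix(g, Tlen, dim(g)[3L])
    alpha <- colMeans(gmat)
    pmax(as.vector(Amat %*% alpha), 0)
}

#' Aggregated multi-layer Grad-CAM heatmap
#'
#' Computes one heatmap per convolutional block, min-max normalizes each
#' (all-zero or constant maps stay zero), linearly resizes all to the input
#' length, and averages them elementwise into the final [0, 1] heatmap.
#'
#' @param model a trained \linkS4class{TrainedModel}
#' @param segment one z-scored input segment
#' @param subjectId,segmentIndex identifiers stored in the result
#' @return an \linkS4class{AttributionMap} of kind "gradcam"
#' @export
gradCamAggregate <- function(model, segment, subjectId = "subject",
                             segmentIndex = 1L) {
    cfg <- model@config
    pass <- .gradCamPass(model, segment)
    L <- cfg@inputLength
    maps <- vapply(seq_len(cfg@nBlocks), function(b) {
        A <- pass$fwd$blocks[[b]]$relu
        g <- pass$taps[[b]]
        Tlen <- dim(A)[2L]
        hm <- pmax(as.vector(matrix(A, Tlen, dim(A)[3L]) %*%
                             colMeans(matrix(g, Tlen, dim(g)[3L]))), 0)
        .resizeLinear(.minmaxNorm(hm), L)
    }, numeric(L))
    final <- rowMeans(maps)
    new("AttributionMap", subjectId = subjectId,
        segmentIndex = as.integer(segmentIndex),
        values = pmin(pmax(final, 0), 1), kind = "gradcam",
        meta = list(layers = cfg@nBlocks))
}

## Multipliers through one max-pool pair via max(a, b) = a + relu(b - a).
## x1/x2: x-side values (B, Lo, C) after broadcasting; b1/b2: background
## values; mo: incoming multipliers (B, Lo, C).
.poolPairMultipliers <- function(x1, x2, b1, b2, mo, eps = 1e-9) {
    ux <- x2 - x1
    ub <- b2 - b1
    du <- ux - ub
    r <- ifelse(abs(du) > eps,
                (pmax(ux, 0) - pmax(ub, 0)) / du,
                as.numeric(ux > 0))
    mu <- mo * r
    list(m1 = mo - mu, m2 = mu)
}

#' Deep-SHAP attribution for one segment
#'
#' Propagates DeepLIFT rescale-rule multipliers against each background
#' segment and averages: linear components (convolutions, inference-mode
#' batch normalization, the linear head) pass multipliers exactly, ReLUs use
#' the rescale rule, and each max-pool is decomposed as
#' \eqn{\max(a,b) = a + \mathrm{relu}(b-a)}. The resulting attributions
#' satisfy completeness: their sum equals \eqn{f(x) - \mathrm{E}_b f(b)}
#' within 1e-3 relative tolerance (verified at emit time; violation is an
#' error).
#'
#' @param model a trained \linkS4class{TrainedModel}
#' @param segment one z-scored input segment
#' @param background matrix of background segments (one per row), e.g.
#'   event-free training segments from \code{\link{quietBackground}}
#' @param subjectId,segmentIndex identifiers stored in the result
#' @return an \linkS4class{AttributionMap} of kind "shap" with signed values
#' @export
deepShap <- function(model, segment, background, subjectId = "subject",
                     segmentIndex = 1L) {
    cfg <- model@config
    if (is.vector(background)) background <- matrix(background, nrow = 1L)
    L <- cfg@inputLength
    if (length(segment) != L) {
        stop("segment length does not match the model input length")
    }
    if (ncol(background) != L) {
        stop("background segment length ", ncol(background),
             " does not match the model input length ", L)
    }
    if (cfg@pool != 2L && cfg@nBlocks > 0L) {
        stop("Deep-SHAP multiplier propagation is implemented for pool size 2")
    }
    B <- nrow(background)
    Xall <- rbind(matrix(segment, nrow = 1L), background)
    fwd <- .nnForwardShap(cfg, model@params, Xall)
    fx <- fwd$pred[1L]
    fb <- fwd$pred[-1L]

    ## head: multipliers = weights, for every background
    D <- prod(fwd$flatDim[2:3])
    m <- matrix(model@params$head$w, B, D, byrow = TRUE)
    dim(m) <- c(B, fwd$flatDim[2L], fwd$flatDim[3L])

    for (b in rev(seq_len(cfg@nBlocks))) {
        cache <- fwd$blocks[[b]]
        p <- model@params$blocks[[b]]
        R <- cache$relu          # post-ReLU pool input, (B+1, T, C)
        Z <- cache$bnY           # pre-ReLU batch-norm output, (B+1, T, C)
        Tlen <- dim(R)[2L]
        Lo <- Tlen %/% cfg@pool
        odd <- seq(1L, Lo * 2L, by = 2L)
        even <- seq(2L, Lo * 2L, by = 2L)
        bcast <- function(A, cols) {
            out <- A[rep(1L, B), cols, , drop = FALSE]
            out
        }
        pm <- .poolPairMultipliers(
            bcast(R, odd), bcast(R, even),
            R[-1L, odd, , drop = FALSE], R[-1L, even, , drop = FALSE], m)
        dR <- array(0, c(B, Tlen, dim(R)[3L]))
        dR[, odd, ] <- pm$m1
        dR[, even, ] <- pm$m2
        ## ReLU rescale rule
        zx <- bcast(Z, seq_len(Tlen))
        zb <- Z[-1L, , , drop = FALSE]
        dz <- zx - zb
        r <- ifelse(abs(dz) > 1e-9,
                    (pmax(zx, 0) - pmax(zb, 0)) / dz,
                    as.numeric(zx > 0))
        dR <- dR * r
        ## inference batch-norm is affine
        mBN <- B * Tlen
        scale <- p$gamma / sqrt(p$rvar + .BN_EPS)
        dZf <- dR; dim(dZf) <- c(mBN, length(scale))
        dZf <- dZf * rep(scale, each = mBN)
        dim(dZf) <- dim(dR)
        ## convolution is linear: data-backward pass
        Cin <- if (b == 1L) 1L else cfg@nFilters
        m <- .convBwdData(dZf, p$W, cfg@kernel, Cin)
    }
    mMat <- matrix(m, B, L)
    phiPer <- mMat * (matrix(segment, B, L, byrow = TRUE) - background)
    phi <- colMeans(phiPer)

    delta <- fx - mean(fb)
    gap <- abs(sum(phi) - delta)
    if (gap > 1e-3 * max(1, abs(delta))) {
        stop(sprintf(
            "Deep-SHAP completeness violated: |sum(phi) - delta| = %.3g for delta = %.3g",
            gap, delta))
    }
    new("AttributionMap", subjectId = subjectId,
        segmentIndex = as.integer(segmentIndex), values = phi, kind = "shap",
        meta = list(background = B, completenessGap = gap,
                    expectedOutput = mean(fb), prediction = fx))
}

## Inference forward keeping the pre-ReLU tap needed by the rescale rule.
.nnForwardShap <- function(cfg, params, X) {
    N <- nrow(X)
    A <- X; dim(A) <- c(N, ncol(X), 1L)
    blocks <- vector("list", cfg@nBlocks)
    for (b in seq_len(cfg@nBlocks)) {
        p <- params$blocks[[b]]
        Z <- .convFwd(A, p$W, p$b, cfg@kernel)$Z
        Y <- .bnFwdInfer(Z, p$gamma, p$beta, p$rmean, p$rvar)
        R <- Y
        R[R < 0] <- 0
        blocks[[b]] <- list(bnY = Y, relu = R)
        A <- .poolFwd(R, cfg@pool)$Y
    }
    flatDim <- dim(A)
    Xf <- A; dim(Xf) <- c(N, prod(flatDim[2:3]))
    list(pred = as.vector(Xf %*% params$head$w) + params$head$b,
         blocks = blocks, flatDim = flatDim)
}

## Convolution data-backward only (multiplier propagation).
.convBwdData <- function(dZ, W, kernel, Cin) {
    d <- dim(dZ); N <- d[1L]; L <- d[2L]
    dim(dZ) <- c(N * L, ncol(W))
    dM <- tcrossprod(dZ, W)
    pad <- (kernel - 1L) %/% 2L
    dAp <- array(0, c(N, L + 2L * pad, Cin))
    for (j in seq_len(kernel)) {
        blk <- dM[, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE]
        dim(blk) <- c(N, L, Cin)
        dAp[, j:(j + L - 1L), ] <- dAp[, j:(j + L - 1L), , drop = FALSE] + blk
    }
    dAp[, (pad + 1L):(pad + L), , drop = FALSE]
}

#' Event-free background segments for Deep-SHAP
#'
#' Selects up to \code{n} segments with an event-count label of zero (quiet
#' breathing as the reference state) from a list of segment sets.
#'
#' @param sets list of \linkS4class{SegmentSet}
#' @param n maximum number of background segments
#' @param seed sampling seed
#' @return matrix with one background segment per row
#' @export
quietBackground <- function(sets, n = 50, seed = 1L) {
    st <- .stackSets(sets)
    zero <- which(st$y == 0)
    if (!length(zero)) stop("no event-free segments available for background")
    picked <- .withSeed(seed, {
        zero[sample.int(length(zero), min(n, length(zero)))]
    })
    st$X[picked, , drop = FALSE]
}

#' Event-localization score of an attribution map
#'
#' Ratio of the mean relevance inside annotated respiratory-event windows
#' (padded by \code{marginSec} so onset/offset transitions count as inside)
#' to the mean relevance elsewhere in the segment. SHAP maps are scored on
#' absolute values. A ratio above 1 means the model's attention concentrates
#' on the events.
#'
#' @param attribution an \linkS4class{AttributionMap}
#' @param annotations the recording's annotation data.frame
#' @param segmentStart segment start time in seconds from record start
#' @param marginSec margin added around each event window (s)
#' @return list: ratio (Inf if the outside mean is zero), insideMean,
#'   outsideMean
#' @export
localizationScore <- function(attribution, annotations, segmentStart,
                              marginSec = 5) {
    v <- attributionValues(attribution)
    if (attributionKind(attribution) == "shap") v <- abs(v)
    L <- length(v)
    segLen <- L / 4
    segEnd <- segmentStart + segLen
    ev <- annotations[annotations$kind %in% c("apnea", "hypopnea"), ,
                      drop = FALSE]
    ev <- ev[ev$onset_sec < segEnd &
             ev$onset_sec + ev$duration_sec > segmentStart, , drop = FALSE]
    if (!nrow(ev)) {
        stop("segment contains no respiratory events; ",
             "filter to event-bearing segments before scoring")
    }
    tRel <- (seq_len(L) - 1) / 4
    inside <- rep(FALSE, L)
    for (i in seq_len(nrow(ev))) {
        lo <- ev$onset_sec[i] - marginSec - segmentStart
        hi <- ev$onset_sec[i] + ev$duration_sec[i] + marginSec - segmentStart
        inside[tRel >= lo & tRel < hi] <- TRUE
    }
    insideMean <- mean(v[inside])
    outsideMean <- if (all(inside)) NA_real_ else mean(v[!inside])
    ratio <- if (is.na(outsideMean)) NA_real_
             else if (outsideMean == 0) Inf
             else insideMean / outsideMean
    list(ratio = ratio, insideMean = insideMean, outsideMean = outsideMean)
}
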