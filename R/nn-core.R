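## Internal neural-network engine.
##
## Activations are 3-D arrays (batch N, temporal length L, channels C).
## Convolutions are computed as im2col matrix products so the heavy lifting
## is BLAS. All randomness (init, shuffling, dropout) draws from R's RNG so
## a single seed makes training bit-reproducible on fixed thread settings.

.BN_EPS <- 1e-5

## -- convolution (stride 1, same padding, odd kernel) ------------------------

.convFwd <- function(A, W, bias, kernel) {
    d <- dim(A); N <- d[1L]; L <- d[2L]; Cin <- d[3L]
    pad <- (kernel - 1L) %/% 2L
    Ap <- array(0, c(N, L + 2L * pad, Cin))
    Ap[, (pad + 1L):(pad + L), ] <- A
    M <- matrix(0, N * L, kernel * Cin)
    for (j in seq_len(kernel)) {
        sl <- Ap[, j:(j + L - 1L), , drop = FALSE]
        dim(sl) <- c(N * L, Cin)
        M[, ((j - 1L) * Cin + 1L):(j * Cin)] <- sl
    }
    Z <- M %*% W
    Z <- Z + rep(bias, each = N * L)
    dim(Z) <- c(N, L, length(bias))
    list(Z = Z, M = M)
}

.convBwd <- function(dZ, M, W, kernel, N, L, Cin) {
    Cout <- ncol(W)
    dim(dZ) <- c(N * L, Cout)
    dW <- crossprod(M, dZ)
    db <- colSums(dZ)
    dM <- tcrossprod(dZ, W)
    pad <- (kernel - 1L) %/% 2L
    dAp <- array(0, c(N, L + 2L * pad, Cin))
    for (j in seq_len(kernel)) {
        blk <- dM[, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE]
        dim(blk) <- c(N, L, Cin)
        dAp[, j:(j + L - 1L), ] <- dAp[, j:(j + L - 1L), , drop = FALSE] + blk
    }
    list(dA = dAp[, (pad + 1L):(pad + L), , drop = FALSE], dW = dW, db = db)
}

## -- batch normalization (statistics over batch x time, per channel) ---------

.bnFwdTrain <- function(Z, gamma, beta, rmean, rvar, momentum = 0.1) {
    d <- dim(Z); m <- d[1L] * d[2L]; C <- d[3L]
    Zf <- Z; dim(Zf) <- c(m, C)
    mu <- colMeans(Zf)
    xc <- Zf - rep(mu, each = m)
    v <- colMeans(xc * xc)
    sdv <- sqrt(v + .BN_EPS)
    xhat <- xc / rep(sdv, each = m)
    Y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
    dim(Y) <- d
    list(Y = Y, xhat = xhat, sdv = sdv,
         rmean = (1 - momentum) * rmean + momentum * mu,
         rvar = (1 - momentum) * rvar + momentum * v)
}

.bnBwdTrain <- function(dY, xhat, sdv, gamma, dims) {
    m <- dims[1L] * dims[2L]; C <- dims[3L]
    dYf <- dY; dim(dYf) <- c(m, C)
    dgamma <- colSums(dYf * xhat)
    dbeta <- colSums(dYf)
    dxhat <- dYf * rep(gamma, each = m)
    dx <- (dxhat - rep(colMeans(dxhat), each = m) -
           xhat * rep(colMeans(dxhat * xhat), each = m)) / rep(sdv, each = m)
    dim(dx) <- dims
    list(dZ = dx, dgamma = dgamma, dbeta = dbeta)
}

.bnFwdInfer <- function(Z, gamma, beta, rmean, rvar) {
    d <- dim(Z); m <- d[1L] * d[2L]
    scale <- gamma / sqrt(rvar + .BN_EPS)
    shift <- beta - rmean * scale
    Zf <- Z; dim(Zf) <- c(m, length(gamma))
    Y <- Zf * rep(scale, each = m) + rep(shift, each = m)
    dim(Y) <- d
    Y
}

## -- max pooling (size = stride = pool; ties keep the earliest sample) -------

.poolFwd <- function(A, pool) {
    d <- dim(A); Lo <- d[2L] %/% pool
    Y <- A[, seq(1L, Lo * pool, by = pool), , drop = FALSE]
    arg <- array(1L, dim(Y))
    if (pool > 1L) {
        for (j in 2:pool) {
            Aj <- A[, seq(j, Lo * pool, by = pool), , drop = FALSE]
            upd <- Aj > Y
            Y[upd] <- Aj[upd]
            arg[upd] <- j
        }
    }
    list(Y = Y, arg = arg, Lin = d[2L])
}

.poolBwd <- function(dY, arg, pool, Lin) {
    d <- dim(dY); Lo <- d[2L]
    dA <- array(0, c(d[1L], Lin, d[3L]))
    for (j in seq_len(pool)) {
        tmp <- array(0, d)
        sel <- arg == j
        tmp[sel] <- dY[sel]
        dA[, seq(j, Lo * pool, by = pool), ] <- tmp
    }
    dA
}

## -- parameter store ----------------------------------------------------------

## He-normal initialization for conv weights; the flattened head starts small.
.nnInit <- function(cfg, seed) {
    .withSeed(seed, {
        params <- list(blocks = vector("list", cfg@nBlocks), head = NULL)
        Cin <- 1L
        L <- cfg@inputLength
        for (b in seq_len(cfg@nBlocks)) {
            Cout <- cfg@nFilters
            fanIn <- cfg@kernel * Cin
            params$blocks[[b]] <- list(
                W = matrix(stats::rnorm(cfg@kernel * Cin * Cout,
                                        sd = sqrt(2 / fanIn)),
                           cfg@kernel * Cin, Cout),
                b = numeric(Cout), gamma = rep(1, Cout), beta = numeric(Cout),
                rmean = numeric(Cout), rvar = rep(1, Cout))
            Cin <- Cout
            L <- L %/% cfg@pool
        }
        D <- L * Cin
        params$head <- list(w = stats::rnorm(D, sd = sqrt(1 / D)), b = 0)
        params
    })
}

## -- forward / backward -------------------------------------------------------

.nnForward <- function(cfg, params, X, training = FALSE, keep = FALSE) {
    N <- nrow(X)
    A <- X; dim(A) <- c(N, ncol(X), 1L)
    blocks <- vector("list", cfg@nBlocks)
    newStats <- vector("list", cfg@nBlocks)
    for (b in seq_len(cfg@nBlocks)) {
        p <- params$blocks[[b]]
        cv <- .convFwd(A, p$W, p$b, cfg@kernel)
        if (training) {
            bn <- .bnFwdTrain(cv$Z, p$gamma, p$beta, p$rmean, p$rvar)
            newStats[[b]] <- list(rmean = bn$rmean, rvar = bn$rvar)
        } else {
            bn <- list(Y = .bnFwdInfer(cv$Z, p$gamma, p$beta, p$rmean, p$rvar))
        }
        R <- bn$Y
        R[R < 0] <- 0
        pl <- .poolFwd(R, cfg@pool)
        A <- pl$Y
        dmask <- NULL
        if (training && cfg@rDrop > 0) {
            mask <- (stats::runif(length(A)) >= cfg@rDrop) / (1 - cfg@rDrop)
            dim(mask) <- dim(A)
            A <- A * mask
            dmask <- mask
        }
        if (keep) {
            blocks[[b]] <- list(M = cv$M, xhat = bn$xhat, sdv = bn$sdv,
                                relu = R, arg = pl$arg, Lin = pl$Lin,
                                dmask = dmask)
        }
    }
    flatDim <- dim(A)
    Xf <- A; dim(Xf) <- c(N, prod(flatDim[2:3]))
    pred <- as.vector(Xf %*% params$head$w) + params$head$b
    list(pred = pred, Xf = Xf, blocks = blocks, newStats = newStats,
         flatDim = flatDim)
}

## dpred: d(loss)/d(prediction) per segment. With tapGrads = TRUE the
## gradient of the output w.r.t. each block's post-ReLU feature map is kept
## (the Grad-CAM tap point).
.nnBackward <- function(cfg, params, fwd, dpred, training = TRUE,
                        tapGrads = FALSE) {
    grads <- list(blocks = vector("list", cfg@nBlocks), head = NULL)
    grads$head <- list(w = as.vector(crossprod(fwd$Xf, dpred)),
                       b = sum(dpred))
    dA <- tcrossprod(dpred, params$head$w)
    dim(dA) <- fwd$flatDim
    taps <- if (tapGrads) vector("list", cfg@nBlocks) else NULL
    for (b in rev(seq_len(cfg@nBlocks))) {
        cache <- fwd$blocks[[b]]
        p <- params$blocks[[b]]
        if (!is.null(cache$dmask)) dA <- dA * cache$dmask
        dR <- .poolBwd(dA, cache$arg, cfg@pool, cache$Lin)
        if (tapGrads) taps[[b]] <- dR
        dR[cache$relu <= 0] <- 0
        dims <- dim(dR)
        if (training) {
            bn <- .bnBwdTrain(dR, cache$xhat, cache$sdv, p$gamma, dims)
            dZ <- bn$dZ; dgamma <- bn$dgamma; dbeta <- bn$dbeta
        } else {
            m <- dims[1L] * dims[2L]
            scale <- p$gamma / sqrt(p$rvar + .BN_EPS)
            dZf <- dR; dim(dZf) <- c(m, length(scale))
            dZf <- dZf * rep(scale, each = m)
            dZ <- dZf; dim(dZ) <- dims
            dgamma <- dbeta <- NULL
        }
        Cin <- if (b == 1L) 1L else cfg@nFilters
        cb <- .convBwd(dZ, cache$M, p$W, cfg@kernel, dims[1L], dims[2L], Cin)
        grads$blocks[[b]] <- list(W = cb$dW, b = cb$db,
                                  gamma = dgamma, beta = dbeta)
        dA <- cb$dA
    }
    list(grads = grads, taps = taps, dX = dA)
}

## Resume the forward pass from block b's post-ReLU feature map (used by the
## finite-difference oracle for attribution gradients). R: array (N, T, C).
.nnForwardFrom <- function(cfg, params, blockIndex, R) {
    A <- .poolFwd(R, cfg@pool)$Y
    if (blockIndex < cfg@nBlocks) {
        for (b in (blockIndex + 1L):cfg@nBlocks) {
            p <- params$blocks[[b]]
            Z <- .convFwd(A, p$W, p$b, cfg@kernel)$Z
            Y <- .bnFwdInfer(Z, p$gamma, p$beta, p$rmean, p$rvar)
            Y[Y < 0] <- 0
            A <- .poolFwd(Y, cfg@pool)$Y
        }
    }
    d <- dim(A)
    Xf <- A; dim(Xf) <- c(d[1L], prod(d[2:3]))
    as.vector(Xf %*% params$head$w) + params$head$b
}

## -- Adam ---------------------------------------------------------------------

.adamInit <- function(params) {
    zero <- function(x) {
        if (is.list(x)) lapply(x, zero) else x * 0
    }
    list(m = zero(params), v = zero(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    upd <- function(p, g, m, v) {
        if (is.null(g)) return(list(p = p, m = m, v = v))
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g * g
        p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
        list(p = p, m = m, v = v)
    }
    for (b in seq_along(params$blocks)) {
        for (f in c("W", "b", "gamma", "beta")) {
            r <- upd(params$blocks[[b]][[f]], grads$blocks[[b]][[f]],
                     state$m$blocks[[b]][[f]], state$v$blocks[[b]][[f]])
            params$blocks[[b]][[f]] <- r$p
            state$m$blocks[[b]][[f]] <- r$m
            state$v$blocks[[b]][[f]] <- r$v
        }
    }
    for (f in c("w", "b")) {
        r <- upd(params$head[[f]], grads$head[[f]],
                 state$m$head[[f]], state$v$head[[f]])
        params$head[[f]] <- r$p
        state$m$head[[f]] <- r$m
        state$v$head[[f]] <- r$v
    }
    list(params = params, state = state)
}
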