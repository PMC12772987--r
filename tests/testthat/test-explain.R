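test_that("Grad-CAM maps are non-negative, bounded, and aligned", {
    tiny <- tinyRun()
    seg <- segmentMatrix(tiny$sets[[5]])[1, ]
    for (b in seq_len(tiny$config@nBlocks)) {
        hm <- gradCamLayer(tiny$model, seg, b)
        expect_true(all(hm >= 0))
    }
    agg <- gradCamAggregate(tiny$model, seg, "s5", 1)
    v <- attributionValues(agg)
    expect_length(v, 1200)
    expect_true(all(v >= 0 & v <= 1))
    expect_error(gradCamLayer(tiny$model, seg, 99), "blockIndex")
})

test_that("a head that ignores the features yields all-zero heatmaps", {
    tiny <- tinyRun()
    m <- tiny$model
    m@params$head$w[] <- 0
    seg <- segmentMatrix(tiny$sets[[1]])[1, ]
    for (b in seq_len(tiny$config@nBlocks)) {
        expect_identical(max(abs(gradCamLayer(m, seg, b))), 0)
    }
    expect_identical(max(abs(attributionValues(
        gradCamAggregate(m, seg)))), 0)
    ## a constant-output model also attributes zero everywhere under SHAP
    bg <- segmentMatrix(tiny$sets[[2]])[1:3, ]
    sh <- deepShap(m, seg, bg)
    expect_identical(max(abs(attributionValues(sh))), 0)
})

test_that("feature-map gradients agree with finite differences", {
    tiny <- tinyRun()
    cfg <- tiny$config
    seg <- segmentMatrix(tiny$sets[[3]])[2, ]
    pass <- apneaflow:::.gradCamPass(tiny$model, seg)
    set.seed(10)
    for (b in c(1L, cfg@nBlocks)) {
        A <- pass$fwd$blocks[[b]]$relu
        g <- pass$taps[[b]]
        ## probe differentiable coordinates: away from the ReLU kink at 0
        ## and from max-pool ties, where a two-sided difference is valid
        Lo <- dim(A)[2L] %/% 2L
        a1 <- A[, seq(1, 2 * Lo, by = 2), , drop = FALSE]
        a2 <- A[, seq(2, 2 * Lo, by = 2), , drop = FALSE]
        gapOK <- abs(a1 - a2) > 0.01
        ok <- array(FALSE, dim(A))
        ok[, seq(1, 2 * Lo, by = 2), ] <- gapOK
        ok[, seq(2, 2 * Lo, by = 2), ] <- gapOK
        ok <- which(ok & A > 0.01)
        for (trial in 1:5) {
            i <- ok[sample(length(ok), 1)]
            eps <- 1e-4
            up <- A; up[i] <- up[i] + eps
            dn <- A; dn[i] <- dn[i] - eps
            fd <- (apneaflow:::.nnForwardFrom(cfg, tiny$model@params, b, up) -
                   apneaflow:::.nnForwardFrom(cfg, tiny$model@params, b, dn)) /
                  (2 * eps)
            expect_lt(abs(g[i] - fd), 1e-4)
        }
    }
})

test_that("a single-block model's final map is its normalized resized map", {
    tiny <- tinyRun()
    cfg <- modelConfig(nBlocks = 1, nFilters = 4, segmentMinutes = 5,
                       rDrop = 0)
    sets <- tiny$sets
    m <- trainModel(buildModel(cfg, seed = 2), sets[1:4], sets[5:6],
                    trainConfig(5, batchSize = 16, maxEpochs = 2, seed = 2))
    seg <- segmentMatrix(sets[[7]])[1, ]
    layer <- gradCamLayer(m, seg, 1)
    norm <- apneaflow:::.minmaxNorm(layer)
    resized <- apneaflow:::.resizeLinear(norm, 1200)
    expect_equal(attributionValues(gradCamAggregate(m, seg)), resized,
                 tolerance = 1e-12)
})

test_that("Deep-SHAP is exact for a linear model", {
    ## a 0-block model is f(x) = w'x + c, whose Shapley values are
    ## w_i (x_i - mu_i) analytically
    cfg <- modelConfig(nBlocks = 0, nFilters = 1, segmentMinutes = 5,
                       rDrop = 0)
    m <- buildModel(cfg, seed = 3)
    set.seed(3)
    w <- rnorm(1200)
    m@params$head$w <- w
    m@params$head$b <- 2.5
    x <- rnorm(1200)
    bg <- matrix(rnorm(10 * 1200), 10)
    sh <- deepShap(m, x, bg)
    expect_equal(attributionValues(sh), w * (x - colMeans(bg)),
                 tolerance = 1e-10)
})

test_that("Deep-SHAP attributions vanish when x equals the background", {
    tiny <- tinyRun()
    seg <- segmentMatrix(tiny$sets[[4]])[1, ]
    sh <- deepShap(tiny$model, seg, matrix(seg, 1))
    expect_lt(max(abs(attributionValues(sh))), 1e-9)
    expect_lt(abs(sum(attributionValues(sh))), 1e-9)
})

test_that("Deep-SHAP completeness holds on trained-model attributions", {
    tiny <- tinyRun()
    bg <- quietBackground(tiny$sets[1:9], 25, seed = 5)
    X <- do.call(rbind, lapply(tiny$sets[10:12],
                               function(s) segmentMatrix(s)))
    set.seed(14)
    rows <- sample(nrow(X), 8)
    for (r in rows) {
        sh <- deepShap(tiny$model, X[r, ], bg)
        delta <- sh@meta$prediction - sh@meta$expectedOutput
        gap <- abs(sum(attributionValues(sh)) - delta)
        expect_lte(gap, 1e-3 * max(1, abs(delta)))
    }
    expect_error(deepShap(tiny$model, X[1, ], matrix(rnorm(100), 1)),
                 "background")
})

test_that("localization scoring summarizes relevance in event windows", {
    uniformMap <- new("AttributionMap", subjectId = "u", segmentIndex = 1L,
                      values = rep(0.5, 1200), kind = "gradcam",
                      meta = list())
    ann <- data.frame(onset_sec = c(30, 100), duration_sec = c(10, 15),
                      kind = c("apnea", "hypopnea"))
    ls <- localizationScore(uniformMap, ann, segmentStart = 0)
    expect_equal(ls$ratio, 1)

    inside <- rep(0, 1200)
    inside[(25 * 4 + 1):(45 * 4)] <- 1   # exactly the padded event window
    insideMap <- new("AttributionMap", subjectId = "i", segmentIndex = 1L,
                     values = inside, kind = "gradcam", meta = list())
    annOne <- data.frame(onset_sec = 30, duration_sec = 10, kind = "apnea")
    ls2 <- localizationScore(insideMap, annOne, segmentStart = 0)
    expect_identical(ls2$ratio, Inf)
    expect_identical(ls2$outsideMean, 0)

    noEvents <- data.frame(onset_sec = 10, duration_sec = 50, kind = "wake")
    expect_error(localizationScore(uniformMap, noEvents, 0),
                 "no respiratory events")
})

test_that("trained-model attributions concentrate on respiratory events", {
    desk <- deskRun()
    bg <- quietBackground(desk$trainSets, 25, seed = 6)
    X <- do.call(rbind, lapply(desk$testSets, segmentMatrix))
    labs <- unlist(lapply(desk$testSets, segmentLabels))
    perSet <- vapply(desk$testSets, function(s) nrow(segmentMatrix(s)),
                     integer(1))
    setOf <- rep(seq_along(desk$testSets), perSet)
    rowIn <- sequence(perSet)
    set.seed(21)
    chosen <- sample(which(labs > 0), 8)
    ratios <- list(gradcam = numeric(0), shap = numeric(0))
    for (r in chosen) {
        rec <- desk$testRecords[[setOf[r]]]
        st <- segmentStarts(desk$testSets[[setOf[r]]])[rowIn[r]]
        gc <- gradCamAggregate(desk$model, X[r, ])
        sh <- deepShap(desk$model, X[r, ], bg)
        ratios$gradcam <- c(ratios$gradcam,
            localizationScore(gc, annotations(rec), st)$ratio)
        ratios$shap <- c(ratios$shap,
            localizationScore(sh, annotations(rec), st)$ratio)
    }
    expect_gt(median(ratios$gradcam), 1)
    expect_gt(median(ratios$shap), 1)
})
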