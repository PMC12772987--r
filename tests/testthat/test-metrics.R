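test_that("ICC matches an independent ANOVA mean-squares oracle", {
    actual <- c(2, 4, 6, 8, 10)
    estimated <- c(2.5, 3.5, 6.5, 7.5, 11)
    got <- icc(actual, estimated)
    ## brute-force two-way ANOVA oracle via stats::aov mean squares
    df <- data.frame(
        y = c(actual, estimated),
        subj = factor(rep(1:5, 2)),
        rater = factor(rep(c("a", "e"), each = 5)))
    ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
    MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
    n <- 5; k <- 2
    oracle <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    expect_lt(abs(got - oracle), 1e-10)
})

test_that("ICC endpoints and guards behave", {
    x <- c(1, 3, 5, 9)
    expect_equal(icc(x, x), 1)
    centered <- x - mean(x)
    expect_lt(icc(centered, -centered), 0)
    expect_error(icc(rep(2, 4), rep(2, 4)), "zero total variance")
    expect_error(icc(1:2, 1:2), "n >= 3")
})

test_that("RMSE matches its formula", {
    expect_identical(rmse(1:5, 1:5), 0)
    expect_equal(rmse(1:5, 1:5 + 3), 3)
    set.seed(4)
    a <- rnorm(50); e <- rnorm(50)
    expect_lt(abs(rmse(a, e) - sqrt(sum((e - a)^2) / 50)), 1e-12)
})

test_that("Bland-Altman limits are mean +/- 1.96 SD of the differences", {
    ident <- blandAltman(c(1, 2, 3), c(1, 2, 3))
    expect_identical(c(ident$meanDiff, ident$loaLow, ident$loaHigh),
                     c(0, 0, 0))
    ba <- blandAltman(c(0, 0), c(-1, 1))
    expect_identical(ba$meanDiff, 0)
    expect_equal(ba$loaHigh, 1.96 * sqrt(2))
    expect_equal(ba$loaLow, -1.96 * sqrt(2))
    ## sign convention: estimated above actual gives positive differences
    over <- blandAltman(c(1, 2, 3), c(2, 3, 5))
    expect_gt(over$meanDiff, 0)
    expect_error(blandAltman(1, 2), "n >= 2")
})

test_that("Cohen's kappa matches hand computation and a reference", {
    expect_identical(cohenKappa(diag(c(3, 5, 2, 4))), 1)
    ## chance-level table: rows proportional to column marginals
    expect_identical(cohenKappa(matrix(c(1, 1, 1, 1), 2)), 0)
    ## po = 4/6, pe = 1/2 -> kappa = 1/3
    expect_equal(cohenKappa(matrix(c(2, 1, 1, 2), 2)), 1 / 3)
    ## independent cross-check on random tables
    skip_if_not_installed("e1071")
    set.seed(6)
    for (i in 1:5) {
        tab <- matrix(rpois(16, 5) + 1, 4)
        expect_equal(cohenKappa(tab),
                     e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    }
})

test_that("kappa handles degenerate concentrated tables", {
    ## all mass on one diagonal cell: expected agreement is 1 and the
    ## table is perfect, so kappa is 1 by convention
    m <- matrix(0, 2, 2); m[1, 1] <- 7
    expect_identical(cohenKappa(m), 1)
    ## all mass on one off-diagonal cell: marginals never coincide, so
    ## expected agreement is 0 and kappa equals the observed agreement, 0
    m2 <- matrix(0, 2, 2); m2[1, 2] <- 7
    expect_identical(cohenKappa(m2), 0)
})

test_that("binary diagnostics reproduce the confusion-cell formulas", {
    perfect <- binaryDiagnostics(c(0.2, 6, 12, 0.5), c(0.1, 7, 11, 0.9), 5)
    expect_identical(perfect$Se, 100)
    expect_identical(perfect$Sp, 100)
    expect_identical(perfect$Acc, 100)
    expect_identical(perfect$PPV, 100)
    expect_identical(perfect$NPV, 100)
    expect_identical(perfect$LRneg, 0)

    ## TP=8, FN=2, TN=9, FP=1 at cutoff 5
    actual <- c(rep(6, 10), rep(1, 10))
    est <- c(rep(6, 8), rep(1, 2), rep(1, 9), 6)
    d <- binaryDiagnostics(actual, est, 5)
    expect_identical(c(d$TP, d$FN, d$TN, d$FP), c(8L, 2L, 9L, 1L))
    expect_equal(d$Se, 80)
    expect_equal(d$Sp, 90)
    expect_equal(d$LRpos, 8)

    ## all predicted positive with mixed truth: Sp = 0 and Se = 1, so
    ## LR- is 0/0 -> flagged undefined rather than silently zero
    allpos <- binaryDiagnostics(c(1, 6, 2, 8), rep(10, 4), 5)
    expect_identical(allpos$Sp, 0)
    expect_identical(allpos$Se, 100)
    expect_true("LRneg" %in% allpos$undefined)
    expect_true(is.na(allpos$LRneg))
    ## mixed predictions missing some positives: LR- genuinely infinite
    somepos <- binaryDiagnostics(c(1, 6, 2, 8), c(10, 2, 10, 10), 5)
    expect_identical(somepos$Sp, 0)
    expect_true(is.infinite(somepos$LRneg))

    ## no actual positives: Se flagged undefined, not silently zero
    nopos <- binaryDiagnostics(c(1, 2), c(1, 2), 5)
    expect_true("Se" %in% nopos$undefined)
    expect_true(is.na(nopos$Se))
})

test_that("binary diagnostics are invariant to monotone relabeling", {
    set.seed(8)
    a <- runif(40, 0, 20)
    e <- pmax(0, a + rnorm(40, sd = 3))
    d1 <- binaryDiagnostics(a, e, 5)
    d2 <- binaryDiagnostics(5 * (a >= 5) + a / 10, 5 * (e >= 5) + e / 10, 5)
    for (f in c("Se", "Sp", "Acc", "PPV", "NPV")) {
        expect_identical(d1[[f]], d2[[f]])
    }
})

test_that("the 4-class confusion matrix preserves counts and order", {
    a <- c("no_osa", "mild", "moderate", "severe", "mild")
    p <- c("no_osa", "moderate", "moderate", "severe", "mild")
    cm <- buildConfusion4(a, p)
    expect_identical(dim(cm), c(4L, 4L))
    expect_identical(sum(cm), 5L)
    expect_identical(cm["mild", "moderate"], 1L)
    expect_identical(unname(diag(cm)), c(1L, 1L, 1L, 1L))
    expect_error(buildConfusion4(c("mild", "bad"), c("mild", "mild")),
                 "unknown")
})

test_that("kappa is not invariant under transpose-symmetrization", {
    ## guard against accidental symmetrization: an asymmetric-marginal table
    ## must give a different kappa from its symmetrized counterpart
    tab <- matrix(c(10, 6, 0, 4), 2)
    sym <- (tab + t(tab)) / 2
    expect_false(isTRUE(all.equal(cohenKappa(tab), cohenKappa(sym))))
})

test_that("the diagnostic report ties the pieces together", {
    set.seed(12)
    a <- runif(40, 0, 20)
    e <- pmax(0, a + rnorm(40, sd = 2))
    rep <- diagnosticReport(a, e)
    expect_identical(rep@n, 40L)
    expect_identical(sum(rep@confusion), 40L)
    expect_equal(rep@acc4, 100 * sum(diag(rep@confusion)) / 40)
    expect_equal(rep@kappa, cohenKappa(rep@confusion))
    expect_equal(rep@rmse, rmse(a, e))
    expect_true(rep@blandAltman$loaLow <= rep@blandAltman$meanDiff)
})
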