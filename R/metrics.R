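## Agreement and diagnostic statistics for method-comparison of AHI
## estimates against the PSG reference.

#' Intraclass correlation coefficient
#'
#' Two-way, single-measure, absolute-agreement ICC (ICC(A,1)) computed from
#' the ANOVA decomposition of the n x 2 rating table (reference and
#' estimate): with row, column, and error mean squares MSR, MSC, MSE over n
#' subjects and k = 2 raters,
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).}
#'
#' @param actual reference values
#' @param estimated estimated values
#' @return ICC in [-1, 1]
#' @export
icc <- function(actual, estimated) {
    if (length(actual) != length(estimated) || length(actual) < 3L) {
        stop("need equal-length vectors with n >= 3")
    }
    X <- cbind(actual, estimated)
    n <- nrow(X); k <- 2
    grand <- mean(X)
    if (sum((X - grand)^2) < 1e-24) {
        stop("zero total variance: ICC undefined")
    }
    rowM <- rowMeans(X)
    colM <- colMeans(X)
    SSR <- k * sum((rowM - grand)^2)
    SSC <- n * sum((colM - grand)^2)
    SSE <- sum((X - grand)^2) - SSR - SSC
    MSR <- SSR / (n - 1)
    MSC <- SSC / (k - 1)
    MSE <- SSE / ((n - 1) * (k - 1))
    (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

#' Root mean squared error
#'
#' @param actual reference values
#' @param estimated estimated values
#' @return RMSE in the units of the inputs (events/hour for AHI)
#' @export
rmse <- function(actual, estimated) {
    if (length(actual) != length(estimated) || !length(actual)) {
        stop("need equal-length non-empty vectors")
    }
    sqrt(mean((estimated - actual)^2))
}

#' Bland-Altman agreement statistics
#'
#' Differences are estimated minus actual; the limits of agreement are the
#' mean difference +/- 1.96 standard deviations (n - 1 denominator).
#'
#' @param actual reference values
#' @param estimated estimated values
#' @return list: meanDiff, loaLow, loaHigh, withinFraction (fraction of
#'   points inside the limits), and the per-subject differences
#' @export
blandAltman <- function(actual, estimated) {
    if (length(actual) != length(estimated) || length(actual) < 2L) {
        stop("need equal-length vectors with n >= 2")
    }
    d <- estimated - actual
    m <- mean(d)
    s <- stats::sd(d)
    lo <- m - 1.96 * s
    hi <- m + 1.96 * s
    list(meanDiff = m, loaLow = lo, loaHigh = hi,
         withinFraction = mean(d >= lo & d <= hi), differences = d)
}

#' Cohen's kappa from a confusion matrix
#'
#' Unweighted chance-corrected agreement,
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}, with observed agreement the
#' diagonal proportion and expected agreement the product of the marginals.
#'
#' @param confusion square matrix of counts (rows actual, columns predicted)
#' @return kappa
#' @export
cohenKappa <- function(confusion) {
    confusion <- as.matrix(confusion)
    if (nrow(confusion) != ncol(confusion)) {
        stop("confusion matrix must be square")
    }
    total <- sum(confusion)
    if (total <= 0 || any(confusion < 0)) {
        stop("confusion matrix needs non-negative counts with a positive total")
    }
    po <- sum(diag(confusion)) / total
    pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
    if (abs(1 - pe) < 1e-12) {
        if (abs(1 - po) < 1e-12) return(1)
        stop("degenerate table: expected agreement is 1 but observed is not")
    }
    (po - pe) / (1 - pe)
}

#' Binary diagnostic metrics at an AHI cutoff
#'
#' Positive means AHI >= cutoff for both the reference and the estimate.
#' Se, Sp, Acc, PPV, and NPV are percentages; LR+ = Se/(1-Sp) and
#' LR- = (1-Se)/Sp use proportions. Metrics whose denominator is empty (no
#' actual positives/negatives, no predicted positives/negatives, or a zero
#' in a likelihood-ratio denominator) are returned as NA or Inf and named in
#' \code{undefined} rather than silently zeroed.
#'
#' @param actualAhi reference AHI values
#' @param estimatedAhi estimated AHI values
#' @param cutoff positive AHI cutoff (1, 5, or 10 e/h clinically)
#' @return list: TP, FP, TN, FN, Se, Sp, Acc, PPV, NPV, LRpos, LRneg,
#'   undefined (character vector of flagged metrics)
#' @export
binaryDiagnostics <- function(actualAhi, estimatedAhi, cutoff) {
    if (length(actualAhi) != length(estimatedAhi)) {
        stop("need equal-length vectors")
    }
    if (cutoff <= 0) stop("cutoff must be > 0")
    ap <- actualAhi >= cutoff
    pp <- estimatedAhi >= cutoff
    TP <- sum(ap & pp); FN <- sum(ap & !pp)
    TN <- sum(!ap & !pp); FP <- sum(!ap & pp)
    undef <- character(0)
    ratio <- function(num, den, name) {
        if (den == 0) {
            undef <<- c(undef, name)
            return(NA_real_)
        }
        num / den
    }
    se <- ratio(TP, TP + FN, "Se")
    sp <- ratio(TN, TN + FP, "Sp")
    ppv <- ratio(TP, TP + FP, "PPV")
    npv <- ratio(TN, TN + FN, "NPV")
    acc <- (TP + TN) / length(actualAhi)
    lrp <- if (is.na(se) || is.na(sp)) {
        undef <- c(undef, "LRpos"); NA_real_
    } else if (sp == 1) {
        undef <- c(undef, "LRpos")
        if (se > 0) Inf else NA_real_
    } else se / (1 - sp)
    lrn <- if (is.na(se) || is.na(sp)) {
        undef <- c(undef, "LRneg"); NA_real_
    } else if (sp == 0) {
        undef <- c(undef, "LRneg")
        if (se < 1) Inf else NA_real_
    } else (1 - se) / sp
    list(TP = TP, FP = FP, TN = TN, FN = FN,
         Se = 100 * se, Sp = 100 * sp, Acc = 100 * acc,
         PPV = 100 * ppv, NPV = 100 * npv,
         LRpos = lrp, LRneg = lrn, undefined = unique(undef))
}

#' 4-class severity confusion matrix
#'
#' Rows are the actual class, columns the predicted class, both in the order
#' no_osa, mild, moderate, severe.
#'
#' @param actualSeverity,predictedSeverity character vectors of severity
#'   classes
#' @return 4 x 4 integer matrix
#' @export
buildConfusion4 <- function(actualSeverity, predictedSeverity) {
    if (length(actualSeverity) != length(predictedSeverity)) {
        stop("need equal-length vectors")
    }
    a <- factor(actualSeverity, levels = .SEVERITY_LEVELS)
    p <- factor(predictedSeverity, levels = .SEVERITY_LEVELS)
    if (any(is.na(a)) || any(is.na(p))) stop("unknown severity label")
    tab <- table(actual = a, predicted = p)
    matrix(as.integer(tab), 4L, 4L, dimnames = dimnames(tab))
}

#' Full agreement and diagnostic report
#'
#' Computes the ICC, RMSE, Bland-Altman limits, 4-class confusion matrix,
#' Cohen's kappa and accuracy, and binary diagnostics at the 1, 5, and
#' 10 e/h cutoffs.
#'
#' @param actualAhi reference AHI values
#' @param estimatedAhi estimated AHI values
#' @return a \linkS4class{DiagnosticReport}
#' @export
diagnosticReport <- function(actualAhi, estimatedAhi) {
    conf <- buildConfusion4(classifySeverity(actualAhi),
                            classifySeverity(estimatedAhi))
    cutoffs <- lapply(c(1, 5, 10), function(co) {
        binaryDiagnostics(actualAhi, estimatedAhi, co)
    })
    names(cutoffs) <- c("1", "5", "10")
    new("DiagnosticReport",
        cutoffs = cutoffs,
        kappa = cohenKappa(conf),
        acc4 = 100 * sum(diag(conf)) / sum(conf),
        icc = icc(actualAhi, estimatedAhi),
        rmse = rmse(actualAhi, estimatedAhi),
        confusion = conf,
        blandAltman = blandAltman(actualAhi, estimatedAhi),
        n = length(actualAhi))
}
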