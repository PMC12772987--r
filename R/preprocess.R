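## Preprocessing: resample to 4 Hz, cut consecutive fixed-length segments,
## z-score each segment, and label it with the number of respiratory events
## whose onset falls inside it. Deliberately nothing else: no filtering or
## artifact removal is ever applied, so the model sees realistic noise.

## Rational approximation p/q of x by continued fractions, relative error
## below tol.
.ratApprox <- function(x, tol = 1e-6) {
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
    r <- x
    for (i in 1:64) {
        a <- floor(r)
        p <- a * p1 + p0; q <- a * q1 + q0
        if (abs(p / q - x) <= tol * x) return(c(p = p, q = q))
        p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
        if (abs(r - a) < 1e-15) break
        r <- 1 / (r - a)
    }
    c(p = p1, q = q1)
}

## Windowed-sinc (Hamming) low-pass FIR: cutoff fc in cycles/sample, odd tap
## count with ~20% transition band around fc.
.sincLowpass <- function(fc, gain = 1) {
    ntaps <- min(2L * ceiling(3.3 / (fc * 0.2)) + 1L, 16383L)
    m <- (ntaps - 1L) / 2L
    k <- (-m):m
    h <- ifelse(k == 0L, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
    h <- h * (0.54 + 0.46 * cos(pi * k / m))
    h / sum(h) * gain
}

#' Resample an airflow series to 4 Hz
#'
#' Rational-factor resampling (zero-stuffing, anti-aliasing windowed-sinc
#' low-pass applied by FFT convolution, decimation). Pure tones below 1 Hz
#' are preserved in amplitude to well within 2%. Only downsampling (or the
#' identity at 4 Hz) is supported.
#'
#' @param samples numeric series
#' @param fsIn input sampling rate in Hz (>= 4)
#' @return numeric series of length \code{round(length(samples) * 4 / fsIn)}
#' @export
resampleTo4Hz <- function(samples, fsIn) {
    if (fsIn < 4) {
        stop("fsIn must be >= 4 Hz; upsampling is not supported")
    }
    if (any(!is.finite(samples))) {
        stop("samples contain non-finite values")
    }
    nOut <- round(length(samples) * 4 / fsIn)
    if (fsIn == 4) {
        return(samples)
    }
    pq <- .ratApprox(4 / fsIn)
    p <- as.integer(pq["p"]); q <- as.integer(pq["q"])
    u <- if (p > 1L) {
        z <- numeric(length(samples) * p)
        z[seq(1L, length(z), by = p)] <- samples
        z
    } else samples
    ## cutoff = min(input, output) Nyquist, in the upsampled rate
    fc <- 0.5 * min(1, p / q) / p
    h <- .sincLowpass(fc, gain = p)
    m <- (length(h) - 1L) / 2L
    y <- stats::convolve(c(u, numeric(2L * m)), rev(h), type = "open")
    y <- y[(2L * m + 1L):(2L * m + length(u))]
    out <- y[seq(1L, length(u), by = q)]
    length(out) <- nOut
    out
}

#' Cut a 4 Hz signal into consecutive fixed-length segments
#'
#' Non-overlapping 5-, 10-, or 20-minute segments (1200, 2400, or 4800
#' samples); a trailing remainder shorter than one segment is dropped.
#'
#' @param samples numeric series sampled at 4 Hz
#' @param segmentMinutes 5, 10, or 20
#' @return list with \code{segments} (matrix, one raw segment per row) and
#'   \code{startTimes} (seconds)
#' @export
segmentSignal <- function(samples, segmentMinutes) {
    segmentMinutes <- as.integer(segmentMinutes)
    if (!segmentMinutes %in% c(5L, 10L, 20L)) {
        stop("segmentMinutes must be 5, 10, or 20")
    }
    L <- segmentMinutes * 60L * 4L
    nSeg <- length(samples) %/% L
    if (nSeg < 1L) {
        stop("signal shorter than one ", segmentMinutes, "-min segment (",
             length(samples), " < ", L, " samples)")
    }
    seg <- matrix(samples[seq_len(nSeg * L)], nrow = nSeg, byrow = TRUE)
    list(segments = seg,
         startTimes = (seq_len(nSeg) - 1) * segmentMinutes * 60)
}

#' Z-score standardization of one segment
#'
#' \code{(x - mean(x)) / sd(x)}; a segment whose standard deviation is below
#' 1e-8 (e.g. a flatlined disconnection) maps to all zeros instead of
#' propagating non-finite values.
#'
#' @param segment numeric vector
#' @return z-scored vector of the same length
#' @export
standardizeSegment <- function(segment) {
    if (!length(segment)) stop("segment is empty")
    s <- stats::sd(segment)
    if (!is.finite(s) || s < 1e-8) {
        return(numeric(length(segment)))
    }
    (segment - mean(segment)) / s
}

#' Per-segment respiratory event counts
#'
#' A segment's label is the number of apnea and hypopnea annotations whose
#' onset falls in [start, start + segmentMinutes * 60). Artifact and wake
#' annotations are never counted; an event spanning a segment boundary is
#' counted once, in the segment containing its onset.
#'
#' @param startTimes segment start times (s)
#' @param segmentMinutes segment length in minutes
#' @param annotations annotation data.frame (onset_sec, duration_sec, kind)
#' @return integer vector of counts, one per segment
#' @export
labelSegments <- function(startTimes, segmentMinutes, annotations) {
    av <- .validAnnotations(annotations)
    if (!isTRUE(av)) stop(av)
    ev <- annotations[annotations$kind %in% c("apnea", "hypopnea"), ,
                      drop = FALSE]
    width <- segmentMinutes * 60
    vapply(startTimes, function(s) {
        sum(ev$onset_sec >= s & ev$onset_sec < s + width)
    }, integer(1))
}

#' Full preprocessing of one recording into a labelled SegmentSet
#'
#' Resamples to 4 Hz, cuts consecutive segments (dropping the trailing
#' remainder), z-scores every segment, and attaches onset-based event-count
#' labels.
#'
#' @param record an \linkS4class{AirflowRecord}
#' @param segmentMinutes 5, 10, or 20
#' @return a \linkS4class{SegmentSet}
#' @examples
#' rec <- simulateRecord(simConfig(duration = 1800, seed = 3), "demo")
#' ss <- makeSegments(rec, 10)
#' segmentLabels(ss)
#' @export
makeSegments <- function(record, segmentMinutes = 10) {
    x4 <- resampleTo4Hz(flowSamples(record), samplingRate(record))
    cut <- segmentSignal(x4, segmentMinutes)
    seg <- t(apply(cut$segments, 1L, standardizeSegment))
    if (nrow(cut$segments) == 1L) seg <- matrix(seg, nrow = 1L)
    labs <- labelSegments(cut$startTimes, segmentMinutes,
                          annotations(record))
    new("SegmentSet", subjectId = subjectId(record),
        segmentMinutes = as.integer(segmentMinutes), segments = seg,
        labels = labs, startTimes = cut$startTimes)
}

#' Preprocess a cohort of recordings
#'
#' @param records list of \linkS4class{AirflowRecord}
#' @param segmentMinutes 5, 10, or 20
#' @return list of \linkS4class{SegmentSet}
#' @export
segmentCohort <- function(records, segmentMinutes = 10) {
    lapply(records, makeSegments, segmentMinutes = segmentMinutes)
}
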