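## Synthetic pediatric airflow with annotated ground truth.
##
## Breathing is a sinusoid with per-breath frequency jitter (+/-10%) and a
## slow amplitude envelope (period 30-120 s, depth 0.1), plus additive
## Gaussian noise. Respiratory events multiply the breathing by a residual
## gain — <=0.05 for apneas (>=90% amplitude reduction), 0.35-0.55 for
## hypopneas (30-90% reduction) — with 1-s cosine tapers placed just outside
## the annotated window, so onset/offset transitions are abrupt enough for
## attribution methods to find while the annotated window itself sits inside
## the AASM amplitude band. Wake is placed as contiguous blocks at the start
## and end of the record plus one mid-night block; events are only placed in
## sleep, which makes the naive per-segment aggregate overestimate the AHI by
## the recording-time/sleep-time ratio (the linear correction's job).

.withSeed <- function(seed, code) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

.emptyAnnotations <- function() {
    data.frame(onset_sec = numeric(0), duration_sec = numeric(0),
               kind = character(0), stringsAsFactors = FALSE)
}

#' Simulation settings constructor
#'
#' Defaults describe a one-hour pediatric recording: 20-30 breaths/min,
#' events of 6-20 s (at least two breath cycles at the slowest rate), 30% of
#' events apneas, 2 artifacts/h, a wake fraction drawn from 0.1-0.2 per
#' record, and mild additive noise.
#'
#' @param fsOut output sampling rate (Hz)
#' @param duration recording length (s)
#' @param breathRateRange breaths/min interval
#' @param targetEventRate respiratory events per hour of sleep (target AHI)
#' @param apneaFraction proportion of events that are apneas
#' @param eventDurationRange event durations (s)
#' @param artifactRate artifacts per hour of recording
#' @param wakeFraction wake proportion; scalar or length-2 sampling interval
#' @param noiseSd additive noise SD relative to unit baseline amplitude
#' @param seed integer seed
#' @return a \linkS4class{SimConfig}
#' @examples
#' cfg <- simConfig(duration = 1200, targetEventRate = 12, seed = 7)
#' rec <- simulateRecord(cfg, "demo")
#' trueAhi(rec)
#' @export
simConfig <- function(fsOut = 32, duration = 3600,
                      breathRateRange = c(20, 30), targetEventRate = 5,
                      apneaFraction = 0.3, eventDurationRange = c(6, 20),
                      artifactRate = 2, wakeFraction = c(0.1, 0.2),
                      noiseSd = 0.04, seed = 1L) {
    new("SimConfig", fsOut = fsOut, duration = duration,
        breathRateRange = breathRateRange, targetEventRate = targetEventRate,
        apneaFraction = apneaFraction,
        eventDurationRange = eventDurationRange, artifactRate = artifactRate,
        wakeFraction = wakeFraction, noiseSd = noiseSd,
        seed = as.integer(seed))
}

#' Construct an airflow recording object
#'
#' @param subjectId subject identifier
#' @param samples numeric airflow series
#' @param fs sampling rate (Hz)
#' @param duration recording duration (s); defaults to length(samples)/fs
#' @param sleepTime total sleep time (s); defaults to duration
#' @param annotations annotation data.frame (onset_sec, duration_sec, kind)
#' @param trueAhi ground-truth AHI (events/hour of sleep), NA when unknown
#' @return an \linkS4class{AirflowRecord}
#' @export
AirflowRecord <- function(subjectId, samples, fs,
                          duration = length(samples) / fs,
                          sleepTime = duration,
                          annotations = .emptyAnnotations(),
                          trueAhi = NA_real_) {
    new("AirflowRecord", subjectId = subjectId, samples = as.numeric(samples),
        fs = fs, duration = duration, sleepTime = sleepTime,
        annotations = annotations, trueAhi = trueAhi)
}

## Wake layout: 40% of wake at record start, 40% at the end, 20% as one block
## at a random position in the middle of the night. Returns sleep intervals.
.wakeLayout <- function(duration, wakeTotal) {
    if (wakeTotal <= 0) {
        return(list(sleep = matrix(c(0, duration), 1L),
                    wake = matrix(numeric(0), 0L, 2L)))
    }
    wStart <- 0.4 * wakeTotal
    wEnd <- 0.4 * wakeTotal
    wMid <- wakeTotal - wStart - wEnd
    midLo <- wStart + 0.25 * (duration - wakeTotal)
    midHi <- duration - wEnd - wMid - 0.25 * (duration - wakeTotal)
    midOn <- if (midHi > midLo) stats::runif(1, midLo, midHi) else midLo
    wake <- rbind(c(0, wStart), c(midOn, midOn + wMid),
                  c(duration - wEnd, duration))
    sleep <- rbind(c(wStart, midOn),
                   c(midOn + wMid, duration - wEnd))
    list(sleep = sleep, wake = wake)
}

## Place nEv non-overlapping windows of the given durations inside the sleep
## intervals, keeping >= gap seconds between windows and >= margin from
## interval edges (room for the 1-s tapers). Rejection sampling.
.placeWindows <- function(intervals, durations, gap = 10, margin = 2,
                          existing = NULL, what = "events") {
    placed <- if (is.null(existing)) matrix(numeric(0), 0L, 2L) else existing
    onsets <- numeric(length(durations))
    lens <- intervals[, 2L] - intervals[, 1L]
    for (i in seq_along(durations)) {
        d <- durations[i]
        ok <- FALSE
        for (try in seq_len(500L)) {
            valid <- which(lens >= d + 2 * margin)
            if (!length(valid)) break
            iv <- valid[sample.int(length(valid), 1L,
                                   prob = lens[valid])]
            o <- stats::runif(1, intervals[iv, 1L] + margin,
                              intervals[iv, 2L] - margin - d)
            if (nrow(placed) == 0L ||
                all(o > placed[, 2L] + gap | o + d < placed[, 1L] - gap)) {
                placed <- rbind(placed, c(o, o + d))
                onsets[i] <- o
                ok <- TRUE
                break
            }
        }
        if (!ok) {
            stop("recording too short to place the requested ", what,
                 ": could not fit window ", i, " of ", length(durations),
                 " (duration ", round(d, 1), " s with ", gap,
                 " s gaps inside the sleep intervals)")
        }
    }
    onsets
}

## Multiplicative gain curve realizing amplitude-reduction events: residual
## gain inside [onset, onset+duration], 1-s cosine tapers immediately before
## the onset and after the offset.
.applyEventGain <- function(gain, t, onset, duration, residual, taper = 1) {
    idx <- which(t >= onset & t < onset + duration)
    gain[idx] <- pmin(gain[idx], residual)
    down <- which(t >= onset - taper & t < onset)
    if (length(down)) {
        u <- (t[down] - (onset - taper)) / taper
        gain[down] <- pmin(gain[down], residual + (1 - residual) *
                           (0.5 + 0.5 * cos(pi * u)))
    }
    up <- which(t >= onset + duration & t < onset + duration + taper)
    if (length(up)) {
        u <- (t[up] - (onset + duration)) / taper
        gain[up] <- pmin(gain[up], residual + (1 - residual) *
                         (0.5 - 0.5 * cos(pi * u)))
    }
    gain
}

#' Simulate one annotated airflow recording
#'
#' Generates a quasi-periodic pediatric airflow signal, injects the requested
#' number of apneas and hypopneas (residual amplitude \eqn{\le 0.05} and
#' 0.35-0.55 of baseline respectively, satisfying the AASM >=90% and 30-90%
#' reduction criteria), movement/disconnection artifacts, and wake blocks.
#' Events are placed only during sleep. Deterministic given the config seed.
#'
#' @param config a \linkS4class{SimConfig}
#' @param subjectId subject identifier
#' @return an \linkS4class{AirflowRecord} with annotations and true AHI
#' @export
simulateRecord <- function(config, subjectId = "sim") {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    .withSeed(config@seed, {
        fs <- config@fsOut
        dur <- config@duration
        n <- round(dur * fs)
        t <- (seq_len(n) - 1) / fs

        wf <- if (length(config@wakeFraction) == 2L) {
            stats::runif(1, config@wakeFraction[1L], config@wakeFraction[2L])
        } else config@wakeFraction
        layout <- .wakeLayout(dur, wf * dur)
        sleepTime <- dur * (1 - wf)

        ## quasi-periodic breathing with per-breath frequency jitter
        f0 <- stats::runif(1, config@breathRateRange[1L],
                           config@breathRateRange[2L]) / 60
        nBreath <- ceiling(dur * f0 * 1.3) + 5L
        breathDur <- (1 / f0) * (1 + stats::runif(nBreath, -0.1, 0.1))
        bounds <- c(0, cumsum(breathDur))
        phase <- stats::approx(bounds, 2 * pi * (0:nBreath), xout = t,
                               rule = 2)$y
        envP <- stats::runif(1, 30, 120)
        env <- 1 + 0.1 * sin(2 * pi * t / envP + stats::runif(1, 0, 2 * pi))
        base <- env * sin(phase)

        ## respiratory events (sleep only)
        nEv <- round(config@targetEventRate * sleepTime / 3600)
        nAp <- round(config@apneaFraction * nEv)
        kinds <- character(0)
        onsets <- durs <- numeric(0)
        eventWin <- matrix(numeric(0), 0L, 2L)
        if (nEv > 0L) {
            durs <- stats::runif(nEv, config@eventDurationRange[1L],
                                 config@eventDurationRange[2L])
            kinds <- sample(c(rep("apnea", nAp), rep("hypopnea", nEv - nAp)))
            onsets <- .placeWindows(layout$sleep, durs, gap = 10, margin = 2,
                                    what = "events")
            eventWin <- cbind(onsets, onsets + durs)
        }
        gain <- rep(1, n)
        residuals <- numeric(length(kinds))
        for (i in seq_along(kinds)) {
            residuals[i] <- if (kinds[i] == "apnea") {
                stats::runif(1, 0.02, 0.05)
            } else {
                stats::runif(1, 0.35, 0.55)
            }
            gain <- .applyEventGain(gain, t, onsets[i], durs[i], residuals[i])
        }

        sig <- base * gain + config@noiseSd * stats::rnorm(n)

        ## artifacts: high-amplitude bursts and flatline disconnections,
        ## kept >= 35 s away from respiratory events so adjacent-baseline
        ## amplitude statistics around events stay clean
        nArt <- round(config@artifactRate * dur / 3600)
        artOn <- artDur <- numeric(0)
        if (nArt > 0L) {
            artTypes <- sample(c("burst", "flatline"), nArt, replace = TRUE)
            artDur <- ifelse(artTypes == "burst", stats::runif(nArt, 2, 5),
                             stats::runif(nArt, 5, 15))
            whole <- matrix(c(0, dur), 1L)
            guarded <- if (nrow(eventWin)) {
                cbind(eventWin[, 1L] - 35, eventWin[, 2L] + 35)
            } else NULL
            artOn <- .placeWindows(whole, artDur, gap = 5, margin = 1,
                                   existing = guarded, what = "artifacts")
            for (i in seq_len(nArt)) {
                idx <- which(t >= artOn[i] & t < artOn[i] + artDur[i])
                if (artTypes[i] == "burst") {
                    amp <- stats::runif(1, 3, 6)
                    sig[idx] <- sig[idx] + amp * stats::rnorm(length(idx), 0, 0.5)
                } else {
                    sig[idx] <- 0
                }
            }
        }

        ann <- data.frame(
            onset_sec = c(onsets, artOn, layout$wake[, 1L]),
            duration_sec = c(durs, artDur,
                             layout$wake[, 2L] - layout$wake[, 1L]),
            kind = c(kinds, rep("artifact", length(artOn)),
                     rep("wake", nrow(layout$wake))),
            stringsAsFactors = FALSE)
        ann <- ann[ann$duration_sec > 0, , drop = FALSE]
        ann <- ann[order(ann$onset_sec), , drop = FALSE]
        rownames(ann) <- NULL

        AirflowRecord(subjectId, sig, fs, duration = dur,
                      sleepTime = sleepTime, annotations = ann,
                      trueAhi = 3600 * nEv / sleepTime)
    })
}

#' Simulate a cohort of recordings with target AHI levels
#'
#' One record per subject; the target event rate of subject i is
#' \code{ahiLevels[i]} and its seed is derived deterministically from the
#' base config seed and the subject index, so the same base seed reproduces
#' the whole cohort bit-identically.
#'
#' @param nSubjects number of subjects (must equal \code{length(ahiLevels)})
#' @param ahiLevels target AHI (events/hour of sleep) per subject
#' @param baseConfig a \linkS4class{SimConfig} supplying all other settings
#' @param idPrefix prefix for generated subject identifiers
#' @return list of \linkS4class{AirflowRecord}
#' @export
simulateCohort <- function(nSubjects, ahiLevels, baseConfig = simConfig(),
                           idPrefix = "S") {
    if (nSubjects != length(ahiLevels)) {
        stop("nSubjects must equal length(ahiLevels)")
    }
    if (any(ahiLevels < 0)) {
        stop("target AHI levels must be non-negative")
    }
    lapply(seq_len(nSubjects), function(i) {
        cfg <- baseConfig
        cfg@targetEventRate <- ahiLevels[i]
        cfg@seed <- as.integer((as.double(baseConfig@seed) + 1009 * i) %%
                               2147483647)
        simulateRecord(cfg, sprintf("%s%03d", idPrefix, i))
    })
}

#' Event amplitude-envelope ratios of a recording
#'
#' For every annotated respiratory event, the RMS amplitude of the signal
#' inside the event window divided by the RMS of the adjacent baseline: up to
#' \code{flankSec} seconds on each side, excluding samples that fall inside
#' any other annotated event or artifact window (padded by the 1.2 s taper
#' guard). Apneas should give ratios <= 0.10 and hypopneas ratios in
#' (0.10, 0.70].
#'
#' @param record an \linkS4class{AirflowRecord}
#' @param flankSec baseline flank length per side (s)
#' @return data.frame with onset_sec, kind, and ratio
#' @export
eventEnvelopeRatios <- function(record, flankSec = 30) {
    ann <- annotations(record)
    ev <- ann[ann$kind %in% c("apnea", "hypopnea"), , drop = FALSE]
    if (nrow(ev) == 0L) {
        return(data.frame(onset_sec = numeric(0), kind = character(0),
                          ratio = numeric(0)))
    }
    fs <- samplingRate(record)
    x <- flowSamples(record)
    t <- (seq_along(x) - 1) / fs
    excl <- ann[ann$kind %in% c("apnea", "hypopnea", "artifact"), ,
                drop = FALSE]
    bad <- rep(FALSE, length(x))
    for (i in seq_len(nrow(excl))) {
        bad[t >= excl$onset_sec[i] - 1.2 &
            t < excl$onset_sec[i] + excl$duration_sec[i] + 1.2] <- TRUE
    }
    ratio <- vapply(seq_len(nrow(ev)), function(i) {
        o <- ev$onset_sec[i]
        e <- o + ev$duration_sec[i]
        inWin <- x[t >= o & t < e]
        flankIdx <- which(((t >= o - flankSec - 10 & t < o) |
                           (t >= e & t < e + flankSec + 10)) & !bad)
        flank <- x[flankIdx]
        if (!length(flank)) return(NA_real_)
        sqrt(mean(inWin^2)) / sqrt(mean(flank^2))
    }, numeric(1))
    data.frame(onset_sec = ev$onset_sec, kind = ev$kind, ratio = ratio,
               stringsAsFactors = FALSE)
}
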