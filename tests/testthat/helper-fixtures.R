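# Shared fixtures, built lazily once per test run. The tiny run is a small
# trained model for fast unit checks; the desk run is the scaled-down
# end-to-end study (simulate cohorts, train the desk preset, fit the
# correction, estimate the held-out test subjects) shared by the
# whole-pipeline and attribution tests.

.fixtures <- new.env(parent = emptyenv())

tinyRun <- function() {
    if (is.null(.fixtures$tiny)) {
        base <- simConfig(duration = 1800, artifactRate = 1, seed = 11)
        recs <- simulateCohort(12, c(0, 2, 4, 6, 8, 10, 12, 14, 16, 18, 5, 15),
                               base)
        sets <- segmentCohort(recs, 5)
        cfg <- modelConfig(nBlocks = 3, nFilters = 8, segmentMinutes = 5,
                           rDrop = 0.1)
        tc <- trainConfig(segmentMinutes = 5, batchSize = 16, maxEpochs = 12,
                          seed = 3)
        model <- trainModel(buildModel(cfg, seed = 3), sets[1:9], sets[10:12],
                            tc)
        .fixtures$tiny <- list(records = recs, sets = sets, model = model,
                               config = cfg)
    }
    .fixtures$tiny
}

deskRun <- function() {
    if (is.null(.fixtures$desk)) {
        seed <- 1L
        set.seed(seed)
        base <- simConfig(duration = 3600, seed = seed)
        trainRecs <- simulateCohort(80, runif(80, 0, 20), base, "TR")
        base@seed <- seed + 500000L
        valRecs <- simulateCohort(20, runif(20, 0, 20), base, "VA")
        base@seed <- seed + 1000000L
        testRecs <- simulateCohort(30, runif(30, 0, 20), base, "TE")
        cfg <- presetConfig("desk", segmentMinutes = 10, rDrop = 0.1)
        tc <- trainConfig(segmentMinutes = 10, maxEpochs = 60, seed = seed)
        pipe <- trainPipeline(trainRecs, valRecs, cfg, tc)
        est <- estimateCohort(pipe$model, pipe$correction, testRecs, 10)
        trainSets <- segmentCohort(trainRecs, 10)
        testSets <- segmentCohort(testRecs, 10)
        .fixtures$desk <- list(
            trainRecords = trainRecs, valRecords = valRecs,
            testRecords = testRecs, trainSets = trainSets,
            testSets = testSets, model = pipe$model,
            correction = pipe$correction, estimates = est)
    }
    .fixtures$desk
}

# Independent sliding-window RMS envelope oracle: event-window RMS over the
# RMS of up to 30 s of clean baseline on each side (skipping samples within
# 1.2 s of any annotated event or artifact).
oracleEnvelopeRatio <- function(record, onset, duration) {
    x <- flowSamples(record)
    fs <- samplingRate(record)
    t <- (seq_along(x) - 1) / fs
    ann <- annotations(record)
    excl <- ann[ann$kind %in% c("apnea", "hypopnea", "artifact"), ,
                drop = FALSE]
    bad <- rep(FALSE, length(x))
    for (i in seq_len(nrow(excl))) {
        bad[t >= excl$onset_sec[i] - 1.2 &
            t < excl$onset_sec[i] + excl$duration_sec[i] + 1.2] <- TRUE
    }
    rmsWin <- sqrt(mean(x[t >= onset & t < onset + duration]^2))
    flank <- x[((t >= onset - 40 & t < onset) |
                (t >= onset + duration & t < onset + duration + 40)) & !bad]
    rmsWin / sqrt(mean(flank^2))
}
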