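## Interchange formats: 16-bit EDF (single "Flow" channel), a plain
## two-column text format, annotation CSVs, and text checkpoints for
## trained runs. All writers produce files the matching reader round-trips.

.padAscii <- function(s, width) {
    s <- substr(s, 1L, width)
    sprintf(paste0("%-", width, "s"), s)
}

#' Write a recording to EDF
#'
#' Minimal EDF: one data record per second, one 16-bit channel labelled
#' \code{"Flow"}. The sampling rate must be a positive integer and the
#' duration a whole number of seconds. Annotations are written to a sidecar
#' CSV at \code{<path>.annotations.csv}.
#'
#' @param record an \linkS4class{AirflowRecord}
#' @param path output file path
#' @param channel channel label
#' @return invisibly, the path
#' @export
writeEdfAirflow <- function(record, path, channel = "Flow") {
    fs <- samplingRate(record)
    if (fs != round(fs) || fs < 1) {
        stop("EDF writer requires an integer sampling rate")
    }
    x <- flowSamples(record)
    spr <- as.integer(fs)
    nRec <- length(x) %/% spr
    if (nRec * spr != length(x)) {
        stop("EDF writer requires a whole number of seconds")
    }
    physMax <- max(max(abs(x)), 1e-6) * 1.0001
    physMin <- -physMax
    digMax <- 32767L
    digMin <- -32767L
    dig <- as.integer(round((x - physMin) / (physMax - physMin) *
                            (digMax - digMin) + digMin))

    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- paste0(
        .padAscii("0", 8L),
        .padAscii(subjectId(record), 80L),
        .padAscii("apneaflow airflow export", 80L),
        .padAscii("01.01.00", 8L),
        .padAscii("00.00.00", 8L),
        .padAscii(as.character(256L + 256L), 8L),
        .padAscii("", 44L),
        .padAscii(as.character(nRec), 8L),
        .padAscii("1", 8L),
        .padAscii("1", 4L))
    sig <- paste0(
        .padAscii(channel, 16L),
        .padAscii("thermistor", 80L),
        .padAscii("au", 8L),
        .padAscii(sprintf("%.6g", physMin), 8L),
        .padAscii(sprintf("%.6g", physMax), 8L),
        .padAscii(as.character(digMin), 8L),
        .padAscii(as.character(digMax), 8L),
        .padAscii("none", 80L),
        .padAscii(as.character(spr), 8L),
        .padAscii("", 32L))
    writeChar(paste0(hdr, sig), con, eos = NULL)
    writeBin(dig[seq_len(nRec * spr)], con, size = 2L, endian = "little")
    writeAnnotations(annotations(record),
                     paste0(path, ".annotations.csv"))
    invisible(path)
}

#' Read a single airflow channel from an EDF file
#'
#' Parses the EDF header, extracts the named channel's samples at its native
#' sampling rate, and scales digital values to physical units. A sidecar
#' annotation CSV at \code{<path>.annotations.csv} is loaded when present;
#' sleep time is then the duration minus annotated wake, and the true AHI is
#' recomputed from the annotations.
#'
#' @param path EDF file path
#' @param channel channel label to extract (default "Flow")
#' @param subjectIdDefault identifier to use when the EDF patient field is
#'   blank
#' @return an \linkS4class{AirflowRecord}
#' @export
readEdfAirflow <- function(path, channel = "Flow",
                           subjectIdDefault = basename(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
    version <- rd(8L)
    patient <- rd(80L)
    rd(80L); rd(8L); rd(8L)
    hdrBytes <- suppressWarnings(as.integer(rd(8L)))
    rd(44L)
    nRec <- suppressWarnings(as.integer(rd(8L)))
    recDur <- suppressWarnings(as.numeric(rd(8L)))
    ns <- suppressWarnings(as.integer(rd(4L)))
    if (is.na(nRec) || is.na(recDur) || is.na(ns) || is.na(hdrBytes) ||
        ns < 1L) {
        stop("corrupt EDF header in ", path)
    }
    field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
    labels <- field(16L)
    field(80L); field(8L)
    physMin <- as.numeric(field(8L))
    physMax <- as.numeric(field(8L))
    digMin <- as.numeric(field(8L))
    digMax <- as.numeric(field(8L))
    field(80L)
    spr <- as.integer(field(8L))
    field(32L)

    ch <- which(labels == channel)
    if (!length(ch)) {
        stop("channel '", channel, "' not found; available: ",
             paste(labels, collapse = ", "))
    }
    ch <- ch[1L]
    samples <- numeric(nRec * spr[ch])
    pos <- 1L
    for (r in seq_len(nRec)) {
        for (s in seq_len(ns)) {
            vals <- readBin(con, "integer", n = spr[s], size = 2L,
                            endian = "little")
            if (s == ch) {
                samples[pos:(pos + spr[ch] - 1L)] <- vals
                pos <- pos + spr[ch]
            }
        }
    }
    gain <- (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
    x <- (samples - digMin[ch]) * gain + physMin[ch]
    fs <- spr[ch] / recDur
    dur <- nRec * recDur

    annPath <- paste0(path, ".annotations.csv")
    ann <- if (file.exists(annPath)) readAnnotations(annPath)
           else .emptyAnnotations()
    wake <- sum(ann$duration_sec[ann$kind == "wake"])
    sleep <- dur - wake
    nEv <- sum(ann$kind %in% c("apnea", "hypopnea"))
    tAhi <- if (nrow(ann) && sleep > 0) 3600 * nEv / sleep else NA_real_
    AirflowRecord(if (nzchar(patient)) patient else subjectIdDefault,
                  x, fs, duration = dur, sleepTime = sleep,
                  annotations = ann, trueAhi = tAhi)
}

#' Write a recording as plain two-column text
#'
#' Columns \code{time_s} and \code{flow}, tab-separated with a header line.
#'
#' @param record an \linkS4class{AirflowRecord}
#' @param path output path
#' @return invisibly, the path
#' @export
writeFlowText <- function(record, path) {
    x <- flowSamples(record)
    df <- data.frame(time_s = (seq_along(x) - 1) / samplingRate(record),
                     flow = x)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Read or write an annotation CSV
#'
#' Header \code{onset_sec,duration_sec,kind}; kinds restricted to apnea,
#' hypopnea, artifact, wake. Malformed rows are reported with their line
#' number.
#'
#' @param path CSV path
#' @return data.frame of annotations
#' @export
readAnnotations <- function(path) {
    ann <- utils::read.csv(path, stringsAsFactors = FALSE)
    req <- c("onset_sec", "duration_sec", "kind")
    if (!all(req %in% names(ann))) {
        stop("annotation file must have header ", paste(req, collapse = ","))
    }
    bad <- which(!is.finite(ann$onset_sec) | !is.finite(ann$duration_sec) |
                 !ann$kind %in% .ANNOTATION_KINDS)
    if (length(bad)) {
        stop("malformed annotation at line ", bad[1L] + 1L, " of ", path,
             if (!ann$kind[bad[1L]] %in% .ANNOTATION_KINDS) {
                 paste0(": unknown kind '", ann$kind[bad[1L]], "'")
             } else "")
    }
    ann[, req]
}

#' @rdname readAnnotations
#' @param annotations annotation data.frame to write
#' @export
writeAnnotations <- function(annotations, path) {
    av <- .validAnnotations(annotations)
    if (!isTRUE(av)) stop(av)
    utils::write.csv(annotations[, c("onset_sec", "duration_sec", "kind")],
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

.CHECKPOINT_VERSION <- 1L

.writeParamVector <- function(con, name, v) {
    writeLines(paste("param", name, length(v)), con)
    writeLines(paste(sprintf("%.17g", as.vector(v)), collapse = " "), con)
}

#' Save a trained run as structured text
#'
#' Writes the model configuration, weights (full precision text), training
#' history, and AHI correction into a checkpoint directory.
#'
#' @param dir checkpoint directory (created if needed)
#' @param model a \linkS4class{TrainedModel}
#' @param correction a \linkS4class{CorrectionModel}
#' @param runConfig optional named list of run settings, stored verbatim
#' @return invisibly, the directory
#' @export
saveRun <- function(dir, model, correction, runConfig = list()) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- model@config
    meta <- list(
        version = .CHECKPOINT_VERSION,
        model = list(nBlocks = cfg@nBlocks, nFilters = cfg@nFilters,
                     kernel = cfg@kernel, pool = cfg@pool,
                     rDrop = cfg@rDrop, inputLength = cfg@inputLength),
        correction = list(slope = correction@slope,
                          intercept = correction@intercept,
                          fitN = correction@fitN),
        bestEpoch = model@bestEpoch,
        run = runConfig)
    yaml::write_yaml(meta, file.path(dir, "config.yaml"))
    con <- file(file.path(dir, "params.txt"), "w")
    on.exit(close(con))
    for (b in seq_len(cfg@nBlocks)) {
        p <- model@params$blocks[[b]]
        for (f in c("W", "b", "gamma", "beta", "rmean", "rvar")) {
            .writeParamVector(con, sprintf("block%d.%s", b, f), p[[f]])
        }
    }
    .writeParamVector(con, "head.w", model@params$head$w)
    .writeParamVector(con, "head.b", model@params$head$b)
    utils::write.csv(model@history, file.path(dir, "history.csv"),
                     row.names = FALSE)
    invisible(dir)
}

#' Load a trained run saved by \code{saveRun}
#'
#' @param dir checkpoint directory
#' @return list with \code{model}, \code{correction}, and \code{runConfig};
#'   predictions from the reloaded model match the original to full text
#'   precision
#' @export
loadRun <- function(dir) {
    cfgPath <- file.path(dir, "config.yaml")
    if (!file.exists(cfgPath)) stop("no checkpoint found in ", dir)
    meta <- yaml::read_yaml(cfgPath)
    if (is.null(meta$version) || meta$version != .CHECKPOINT_VERSION) {
        stop("checkpoint version mismatch: found ",
             if (is.null(meta$version)) "none" else meta$version,
             ", expected ", .CHECKPOINT_VERSION)
    }
    mc <- meta$model
    cfg <- modelConfig(nBlocks = mc$nBlocks, nFilters = mc$nFilters,
                       segmentMinutes = mc$inputLength %/% 240L,
                       kernel = mc$kernel, pool = mc$pool, rDrop = mc$rDrop)
    lines <- readLines(file.path(dir, "params.txt"))
    vals <- list()
    i <- 1L
    while (i < length(lines)) {
        hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
        n <- as.integer(hdr[3L])
        vals[[hdr[2L]]] <- as.numeric(strsplit(lines[i + 1L], " ",
                                               fixed = TRUE)[[1L]])
        if (length(vals[[hdr[2L]]]) != n) {
            stop("corrupt checkpoint: parameter ", hdr[2L])
        }
        i <- i + 2L
    }
    params <- list(blocks = vector("list", cfg@nBlocks), head = NULL)
    Cin <- 1L
    for (b in seq_len(cfg@nBlocks)) {
        g <- function(f) vals[[sprintf("block%d.%s", b, f)]]
        params$blocks[[b]] <- list(
            W = matrix(g("W"), cfg@kernel * Cin, cfg@nFilters),
            b = g("b"), gamma = g("gamma"), beta = g("beta"),
            rmean = g("rmean"), rvar = g("rvar"))
        Cin <- cfg@nFilters
    }
    params$head <- list(w = vals[["head.w"]], b = vals[["head.b"]])
    history <- utils::read.csv(file.path(dir, "history.csv"))
    model <- new("TrainedModel", config = cfg, params = params,
                 history = history,
                 bestEpoch = as.integer(meta$bestEpoch))
    correction <- new("CorrectionModel", slope = meta$correction$slope,
                      intercept = meta$correction$intercept,
                      fitN = as.integer(meta$correction$fitN))
    list(model = model, correction = correction, runConfig = meta$run)
}
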