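#' Read a barcode count matrix and sample sheet from delimited text
#'
#' The matrix file has the barcode identifier in the first column and one
#' column per sample with a header row. The sample sheet maps each sample
#' name to its role, dorso-ventral position and spike-in total, with
#' columns `sample`, `role`, `position`, `spikein`.
#'
#' @param matrixFile path to the count matrix (TSV by default)
#' @param sampleSheet path to the sample sheet (TSV)
#' @param sep field separator
#' @param normalized whether the stored counts are already spike-in
#'   normalized
#' @return A \linkS4class{BarcodeExperiment}.
#' @export
readBarcodeExperiment <- function(matrixFile, sampleSheet, sep = "\t",
                                  normalized = FALSE) {
    m <- utils::read.table(matrixFile, header = TRUE, sep = sep,
                           row.names = 1L, check.names = FALSE)
    ss <- utils::read.table(sampleSheet, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("sample", "role", "spikein")
    if (!all(need %in% colnames(ss)))
        stop("sample sheet needs columns: ", paste(need, collapse = ", "))
    if (!all(colnames(m) %in% ss$sample))
        stop("every matrix column must appear in the sample sheet")
    ss <- ss[match(colnames(m), ss$sample), ]
    BarcodeExperiment(as.matrix(m), role = ss$role, spikein = ss$spikein,
                      position = if ("position" %in% colnames(ss))
                          ss$position else NULL,
                      normalized = normalized)
}

#' Write a BarcodeExperiment to delimited text
#'
#' Writes the count matrix (barcode IDs in the first column) and, if
#' `sampleSheet` is given, a matching sample sheet.
#'
#' @param x a \linkS4class{BarcodeExperiment}
#' @param matrixFile output path for the count matrix
#' @param sampleSheet optional output path for the sample sheet
#' @param sep field separator
#' @return invisibly, `matrixFile`
#' @export
writeBarcodeExperiment <- function(x, matrixFile, sampleSheet = NULL,
                                   sep = "\t") {
    m <- data.frame(barcode = rownames(x), bcCounts(x), check.names = FALSE)
    utils::write.table(m, matrixFile, sep = sep, quote = FALSE,
                       row.names = FALSE)
    if (!is.null(sampleSheet)) {
        cd <- colData(x)
        ss <- data.frame(sample = colnames(x), role = cd$role,
                         position = cd$position, spikein = cd$spikein)
        utils::write.table(ss, sampleSheet, sep = sep, quote = FALSE,
                           row.names = FALSE)
    }
    invisible(matrixFile)
}

#' Write a FilterReport as TSV
#' @param report a \linkS4class{FilterReport}
#' @param file output path
#' @return invisibly, `file`
#' @export
writeFilterReport <- function(report, file) {
    utils::write.table(filterStages(report), file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read / write single-channel images as TIFF
#'
#' Thin wrappers around the tiff package. Intensities are stored as
#' 16-bit after clamping to [0, 1]; `readImageTiff` returns a plain
#' numeric matrix in [0, 1].
#'
#' @param file path to a TIFF file
#' @return `readImageTiff`: numeric matrix; `writeImageTiff`: invisibly,
#'   `file`.
#' @export
readImageTiff <- function(file) {
    img <- tiff::readTIFF(file)
    if (length(dim(img)) == 3L)
        img <- img[, , 1L]
    img
}

#' @rdname readImageTiff
#' @param image numeric matrix with intensities in [0, 1]
#' @export
writeImageTiff <- function(image, file) {
    img <- pmin(pmax(image, 0), 1)
    tiff::writeTIFF(img, file, bits.per.sample = 16L)
    invisible(file)
}

#' Read / write a SweepSet as long-format delimited text
#'
#' One row per sample with columns `protocol` (`step`, `ramp`, `step200`),
#' `sweep` (the step current in pA for the step family, 0 otherwise),
#' `time` (s) and `voltage` (mV). Protocol constants travel in a header
#' of `#key value` comment lines.
#'
#' @param x a \linkS4class{SweepSet}
#' @param file output path
#' @return `writeSweepSet`: invisibly `file`; `readSweepSet`: a
#'   \linkS4class{SweepSet}.
#' @export
writeSweepSet <- function(x, file) {
    con <- file(file, "w")
    on.exit(close(con))
    hdr <- c(samplingRate = x@samplingRate, rampSlope = x@rampSlope,
             rampStart = x@rampStart, stepStart = x@stepStart,
             stepDur = x@stepDur, bridgeBalance = x@bridgeBalance)
    writeLines(sprintf("#%s %.10g", names(hdr), hdr), con)
    if (length(x@stimTimes))
        writeLines(paste("#stimTimes", paste(x@stimTimes, collapse = ",")), con)
    dt <- 1 / x@samplingRate
    blocks <- c(
        lapply(seq_along(x@stepCurrents), function(j) {
            v <- x@stepTraces[, j]
            data.frame(protocol = "step", sweep = x@stepCurrents[j],
                       time = (seq_along(v) - 1L) * dt, voltage = v)
        }),
        list(data.frame(protocol = "ramp", sweep = 0,
                        time = (seq_along(x@rampTrace) - 1L) * dt,
                        voltage = x@rampTrace),
             data.frame(protocol = "step200", sweep = 200,
                        time = (seq_along(x@step200Trace) - 1L) * dt,
                        voltage = x@step200Trace)))
    utils::write.table(do.call(rbind, blocks), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeSweepSet
#' @export
readSweepSet <- function(file) {
    lines <- readLines(file)
    hdrLines <- grep("^#", lines, value = TRUE)
    kv <- strsplit(sub("^#", "", hdrLines), " ", fixed = TRUE)
    hdr <- stats::setNames(lapply(kv, function(p) p[2L]),
                           vapply(kv, `[`, "", 1L))
    num <- function(k, default = NA_real_)
        if (!is.null(hdr[[k]])) as.numeric(hdr[[k]]) else default
    d <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
    stepD <- d[d$protocol == "step", ]
    currents <- sort(unique(stepD$sweep))
    traces <- vapply(currents,
                     function(I) stepD$voltage[stepD$sweep == I],
                     numeric(sum(stepD$sweep == currents[1L])))
    stim <- if (!is.null(hdr[["stimTimes"]]))
        as.numeric(strsplit(hdr[["stimTimes"]], ",")[[1L]]) else numeric(0)
    new("SweepSet",
        samplingRate = num("samplingRate"),
        stepCurrents = currents,
        stepTraces = traces,
        rampTrace = d$voltage[d$protocol == "ramp"],
        rampSlope = num("rampSlope", 50),
        rampStart = num("rampStart", 0),
        step200Trace = d$voltage[d$protocol == "step200"],
        stepStart = num("stepStart", 0),
        stepDur = num("stepDur", 1),
        stimTimes = stim,
        bridgeBalance = num("bridgeBalance", 0),
        groundTruth = list())
}
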