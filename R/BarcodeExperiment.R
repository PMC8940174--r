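#' Construct a BarcodeExperiment
#'
#' @param counts non-negative numeric matrix, barcodes x samples. Column
#'   names are the sample names (e.g. dMEC, vMEC, isocortex, CNU,
#'   OlfCtxsp, dHip, vHip, control).
#' @param role character vector, one of `"injection"`, `"telencephalic"`,
#'   `"hippocampal"`, `"control"` per sample.
#' @param spikein positive spike-in RNA total per sample.
#' @param position optional dorso-ventral position per sample
#'   (`"dorsal"`, `"ventral"` or NA); required for the two injection and
#'   two hippocampal samples if origin classification or topography is
#'   to be computed.
#' @param normalized logical; whether `counts` are already spike-in
#'   normalized.
#'
#' @return A \linkS4class{BarcodeExperiment}.
#' @examples
#' be <- exampleBarcodeExperiment()
#' be
#' @export
BarcodeExperiment <- function(counts, role, spikein, position = NULL,
                              normalized = FALSE) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("BC%05d", seq_len(nrow(counts)))
    if (is.null(position))
        position <- rep(NA_character_, ncol(counts))
    cd <- S4Vectors::DataFrame(role = as.character(role),
                               position = as.character(position),
                               spikein = as.numeric(spikein),
                               row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    obj <- new("BarcodeExperiment", se)
    metadata(obj)$normalized <- isTRUE(normalized)
    validObject(obj)
    obj
}

#' A tiny example BarcodeExperiment
#'
#' Eight hand-written barcodes over the standard eight samples, raw
#' counts, used in documentation examples and quick interactive checks.
#' @return A \linkS4class{BarcodeExperiment} with 8 barcodes.
#' @export
exampleBarcodeExperiment <- function() {
    m <- rbind(
        c(5000,  100, 500,   0,  20, 300,  10, 0),
        c( 800, 4000,   0, 250,   0,   5, 400, 0),
        c(   0,    0, 120,   0,   0,  80,   0, 0),   # orphan
        c(3000,   50,   0,   0,   0, 900, 100, 0),   # hippocampus-only targets
        c( 200,   30,  60,   0,   0,  40,   0, 0),   # low injection
        c(6000,  200,   4,   2,   1,   3,   2, 1),   # low targets
        c(  90, 7000, 800, 100,   0,  20, 600, 0),
        c( 100,   80, 900,   0,   0,   0,   0, 0))   # exceeds injection
    colnames(m) <- c("dMEC", "vMEC", "isocortex", "CNU", "OlfCtxsp",
                     "dHip", "vHip", "control")
    BarcodeExperiment(
        m,
        role = c("injection", "injection", "telencephalic", "telencephalic",
                 "telencephalic", "hippocampal", "hippocampal", "control"),
        spikein = rep(1000, 8),
        position = c("dorsal", "ventral", NA, NA, NA, "dorsal", "ventral", NA))
}

## ---- internal column selectors ------------------------------------------

.roleCols <- function(x, role) which(colData(x)$role == role)
.injCols <- function(x) .roleCols(x, "injection")
.telCols <- function(x) .roleCols(x, "telencephalic")
.hipCols <- function(x) .roleCols(x, "hippocampal")
.ctrlCols <- function(x) .roleCols(x, "control")
.targetCols <- function(x) c(.telCols(x), .hipCols(x))

.posCol <- function(x, role, position) {
    cd <- colData(x)
    i <- which(cd$role == role & !is.na(cd$position) & cd$position == position)
    if (length(i) != 1L)
        stop(sprintf("need exactly one %s sample with position '%s'",
                     role, position))
    i
}

.injSum <- function(x) {
    cts <- assay(x, "counts")
    rowSums(cts[, .injCols(x), drop = FALSE])
}

## ---- accessors ----------------------------------------------------------

#' @describeIn BarcodeExperiment counts matrix accessor
#' @param x a BarcodeExperiment
#' @export
bcCounts <- function(x) assay(x, "counts")

#' @describeIn BarcodeExperiment per-sample roles
#' @export
sampleRoles <- function(x) as.character(colData(x)$role)

#' @describeIn BarcodeExperiment per-sample spike-in totals
#' @export
spikeIns <- function(x) {
    s <- colData(x)$spikein
    names(s) <- colnames(x)
    s
}

#' @describeIn BarcodeExperiment has spike-in normalization been applied?
#' @export
isNormalized <- function(x) isTRUE(metadata(x)$normalized)

setMethod("show", "BarcodeExperiment", function(object) {
    cat(sprintf("BarcodeExperiment: %d barcodes x %d samples (%s counts)\n",
                nrow(object), ncol(object),
                if (isNormalized(object)) "spike-in normalized" else "raw"))
    r <- sampleRoles(object)
    cat("  samples:",
        paste(sprintf("%s[%s]", colnames(object), substr(r, 1, 3)),
              collapse = " "), "\n")
})

setMethod("show", "FilterReport", function(object) {
    st <- object@stages
    cat("FilterReport:", nrow(st), "stages,",
        if (nrow(st)) sum(st$n_removed) else 0L, "barcodes removed\n")
    if (nrow(st))
        print(st, row.names = FALSE)
})

setMethod("show", "FeatureSet", function(object) {
    cat("FeatureSet:\n")
    cat(sprintf("  RMP %.1f mV | Rin %.1f MOhm | sag %.3f | bridge %.1f MOhm\n",
                object@rmp, object@rin, object@sagRatio, object@bridge))
    cat(sprintf("  rheobase %s pA | threshold %.1f mV | AHP %.1f mV | HW %.2f ms\n",
                if (isTRUE(object@rheobaseCensored)) "> ramp max"
                else sprintf("%.0f", object@rheobase),
                object@apThreshold, object@ahp, object@halfWidth))
    cat(sprintf("  firing %.1f Hz | max %.1f Hz | base %.1f Hz\n",
                object@firingFreq, object@maxFreq, object@baseFreq))
})

setMethod("show", "PspResult", function(object) {
    cat(sprintf(
        "PspResult: %s (p = %.4g), amplitude %.2f mV, latency %.2f +/- %.2f ms, %s, %d trials\n",
        if (object@responsive) "responsive" else "non-responsive",
        object@pValue, object@amplitude, object@meanLatency,
        object@latencySd, object@polarity, object@nTrials))
})

setMethod("show", "RadialProfile", function(object) {
    cat(sprintf("RadialProfile: %d bins%s\n", length(object@binMeans),
                if (object@normalizedValid) "" else " (unnormalized: no signal)"))
})

setMethod("show", "DensityPair", function(object) {
    cat(sprintf("DensityPair: %s %.4f (%.3f) vs %s %.4f (%.3f)\n",
                object@labels[1], object@raw[1], object@normalized[1],
                object@labels[2], object@raw[2], object@normalized[2]))
})

#' FilterReport stage table accessor
#' @param x a \linkS4class{FilterReport}
#' @return data.frame with columns stage, n_in, n_removed, threshold
#' @export
filterStages <- function(x) x@stages

#' Convert a FeatureSet to a one-row data.frame
#' @param x a \linkS4class{FeatureSet}
#' @return one-row data.frame of the intrinsic properties
#' @export
featureTable <- function(x) {
    data.frame(rmp = x@rmp, rin = x@rin, sagRatio = x@sagRatio,
               rheobase = x@rheobase, rheobaseCensored = x@rheobaseCensored,
               apThreshold = x@apThreshold, ahp = x@ahp,
               halfWidth = x@halfWidth, firingFreq = x@firingFreq,
               maxFreq = x@maxFreq, baseFreq = x@baseFreq, bridge = x@bridge)
}
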