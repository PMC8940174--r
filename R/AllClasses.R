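#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData
NULL

#' BarcodeExperiment: barcode-by-sample count container
#'
#' A \linkS4class{SummarizedExperiment} holding one `counts` assay
#' (rows = barcodes, columns = dissected samples) together with the
#' per-sample metadata the projection-mapping pipeline needs:
#' the role of each sample (`injection`, `telencephalic`, `hippocampal`
#' or `control`), its dorso-ventral position where applicable, and the
#' spike-in RNA total used for cross-sample normalization.
#'
#' Validity requires exactly two injection samples (dorsal and ventral
#' entorhinal dissections), three telencephalic target samples, two
#' hippocampal target samples and at least one negative control;
#' all counts must be non-negative and all spike-in totals positive.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; `metadata()$normalized`
#'   records whether spike-in normalization has been applied.
#' @aliases BarcodeExperiment-class
#' @exportClass BarcodeExperiment
setClass("BarcodeExperiment", contains = "SummarizedExperiment")

.validBarcodeExperiment <- function(object) {
    msg <- character(0)
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- colData(object)
    for (col in c("role", "spikein"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (length(msg))
        return(msg)
    role <- as.character(cd$role)
    bad <- setdiff(role, c("injection", "telencephalic", "hippocampal", "control"))
    if (length(bad))
        msg <- c(msg, sprintf("unknown sample role(s): %s",
                              paste(unique(bad), collapse = ", ")))
    if (sum(role == "injection") != 2L)
        msg <- c(msg, "exactly two injection samples (dMEC, vMEC) required")
    if (sum(role == "telencephalic") != 3L)
        msg <- c(msg, "exactly three telencephalic target samples required")
    if (sum(role == "hippocampal") != 2L)
        msg <- c(msg, "exactly two hippocampal target samples required")
    if (sum(role == "control") < 1L)
        msg <- c(msg, "at least one control sample required")
    cts <- assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0))
        msg <- c(msg, "counts must be finite and non-negative")
    if (any(!is.finite(cd$spikein)) || any(cd$spikein <= 0))
        msg <- c(msg, "spike-in totals must be positive")
    if (length(msg)) msg else TRUE
}
setValidity("BarcodeExperiment", .validBarcodeExperiment)

#' FilterReport: per-stage audit of the barcode filtering pipeline
#'
#' Records, for each pipeline stage in order, how many barcodes entered,
#' how many were removed, and the threshold in force (NA where the stage
#' has none). Removals always sum to the difference between the initial
#' and final row counts.
#'
#' @slot stages data.frame with columns `stage`, `n_in`, `n_removed`,
#'   `threshold`.
#' @exportClass FilterReport
setClass("FilterReport", representation(stages = "data.frame"))

setValidity("FilterReport", function(object) {
    st <- object@stages
    need <- c("stage", "n_in", "n_removed", "threshold")
    if (!all(need %in% colnames(st)))
        return("stages must have columns stage, n_in, n_removed, threshold")
    if (nrow(st) && any(st$n_removed < 0))
        return("removals must be non-negative")
    if (nrow(st) > 1L &&
        !all(st$n_in[-1L] == st$n_in[-nrow(st)] - st$n_removed[-nrow(st)]))
        return("stage n_in must chain: n_in[i+1] = n_in[i] - n_removed[i]")
    TRUE
})

#' SweepSet: a current-clamp recording session for one cell
#'
#' Holds the three protocols the intrinsic-property analysis uses:
#' a family of 1-s current steps (typically -40 to +40 pA in 20-pA
#' increments), a depolarizing current ramp (50 pA/s to 400 pA), and a
#' 1-s 200-pA step used for firing-frequency measures. Optionally holds
#' light-stimulus onset times and the recorded bridge balance.
#'
#' @slot samplingRate sampling rate in Hz
#' @slot stepCurrents injected step currents in pA, one per column of
#'   `stepTraces`
#' @slot stepTraces matrix of membrane voltage (mV), samples x steps
#' @slot rampTrace voltage trace (mV) for the ramp protocol
#' @slot rampSlope ramp slope in pA/s
#' @slot rampStart ramp onset within `rampTrace`, seconds
#' @slot step200Trace voltage trace (mV) for the 1-s 200-pA step
#' @slot stepStart step onset in the step-family and 200-pA traces, seconds
#' @slot stepDur step duration, seconds
#' @slot stimTimes optional light-pulse onsets, seconds
#' @slot bridgeBalance bridge balance, MOhm
#' @slot groundTruth list of generator ground-truth parameters (empty for
#'   recorded data)
#' @exportClass SweepSet
setClass("SweepSet", representation(
    samplingRate = "numeric",
    stepCurrents = "numeric",
    stepTraces = "matrix",
    rampTrace = "numeric",
    rampSlope = "numeric",
    rampStart = "numeric",
    step200Trace = "numeric",
    stepStart = "numeric",
    stepDur = "numeric",
    stimTimes = "numeric",
    bridgeBalance = "numeric",
    groundTruth = "list"
))

setValidity("SweepSet", function(object) {
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
        return("samplingRate must be a single positive number")
    if (ncol(object@stepTraces) != length(object@stepCurrents))
        return("one step trace per step current required")
    if (!any(object@stepCurrents > 0) || !any(object@stepCurrents < 0))
        return("step currents must include depolarizing and hyperpolarizing values")
    if (any(!is.finite(object@stepTraces)) || any(!is.finite(object@rampTrace)) ||
        any(!is.finite(object@step200Trace)))
        return("all traces must be finite")
    TRUE
})

#' FeatureSet: intrinsic electrophysiological properties of one cell
#'
#' All voltages in mV, resistances in MOhm, times in ms, frequencies in Hz.
#' Properties that cannot be measured (e.g. no spike by the end of the
#' ramp) are NA.
#'
#' @slot rmp resting membrane potential (mV)
#' @slot rin input resistance (MOhm)
#' @slot sagRatio steady-state over peak deflection on the largest
#'   hyperpolarizing step
#' @slot rheobase minimal spike-evoking current (pA); NA with
#'   `rheobaseCensored=TRUE` means "> max ramp current"
#' @slot rheobaseCensored logical, TRUE when no spike occurred by the ramp end
#' @slot apThreshold action-potential threshold (mV)
#' @slot ahp after-hyperpolarization depth below threshold (mV)
#' @slot halfWidth AP width at half spike amplitude (ms)
#' @slot firingFreq spikes per second on the 1-s 200-pA step (Hz)
#' @slot maxFreq instantaneous frequency of the first inter-spike interval (Hz)
#' @slot baseFreq instantaneous frequency of the last inter-spike interval (Hz)
#' @slot bridge bridge balance (MOhm)
#' @exportClass FeatureSet
setClass("FeatureSet", representation(
    rmp = "numeric", rin = "numeric", sagRatio = "numeric",
    rheobase = "numeric", rheobaseCensored = "logical",
    apThreshold = "numeric", ahp = "numeric", halfWidth = "numeric",
    firingFreq = "numeric", maxFreq = "numeric", baseFreq = "numeric",
    bridge = "numeric"
))

#' PspResult: quantification of an optogenetically evoked PSP
#'
#' @slot responsive logical; TRUE when the paired test of per-trial peak
#'   versus baseline is significant
#' @slot pValue p-value of the responsiveness test
#' @slot amplitude mean peak-minus-baseline deflection (mV, signed)
#' @slot meanLatency mean onset latency after the stimulus (ms)
#' @slot latencySd trial-to-trial SD of the onset latency (ms); reported
#'   only for responses exceeding 1 mV
#' @slot polarity "depolarizing", "hyperpolarizing" or "biphasic"
#' @slot nTrials number of trials analysed
#' @exportClass PspResult
setClass("PspResult", representation(
    responsive = "logical", pValue = "numeric", amplitude = "numeric",
    meanLatency = "numeric", latencySd = "numeric", polarity = "character",
    nTrials = "integer"
))

#' RadialProfile: binned fluorescence profile across the CA1 radial axis
#'
#' @slot binMeans raw per-bin mean intensities
#' @slot normalized per-bin means scaled so the maximum is 1 (NA-filled
#'   with `normalizedValid=FALSE` when the ROI carries no signal)
#' @slot binEdges bin boundaries in pixels along the radial axis
#' @slot normalizedValid logical
#' @exportClass RadialProfile
setClass("RadialProfile", representation(
    binMeans = "numeric", normalized = "numeric", binEdges = "numeric",
    normalizedValid = "logical"
))

#' DensityPair: thresholded axon densities for two regions
#'
#' Raw densities are the fraction of pixels above threshold in each
#' region; the normalized pair is scaled to sum to 1 within the brain.
#'
#' @slot labels the two region labels
#' @slot raw raw densities, in [0, 1]
#' @slot normalized normalized pair summing to 1
#' @exportClass DensityPair
setClass("DensityPair", representation(
    labels = "character", raw = "numeric", normalized = "numeric"
))

setValidity("DensityPair", function(object) {
    if (length(object@raw) != 2L || length(object@normalized) != 2L)
        return("raw and normalized must each hold two values")
    if (any(object@raw < 0) || any(object@raw > 1))
        return("raw densities must lie in [0, 1]")
    if (abs(sum(object@normalized) - 1) > 1e-8)
        return("normalized pair must sum to 1")
    TRUE
})
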