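#' Spike-in normalization of barcode counts
#'
#' Scales each sample's counts by (reference spike-in / sample spike-in),
#' with the reference taken as the maximum spike-in total across samples
#' so that all scale factors are >= 1. Within-sample barcode ratios are
#' unchanged. Sets the `normalized` flag.
#'
#' @param x a raw \linkS4class{BarcodeExperiment}
#' @return The normalized \linkS4class{BarcodeExperiment}.
#' @export
normalizeBySpikein <- function(x) {
    if (isNormalized(x))
        stop("table is already spike-in normalized")
    s <- spikeIns(x)
    if (any(s <= 0))
        stop("spike-in totals must be positive")
    scale <- max(s) / s
    cts <- sweep(bcCounts(x), 2L, scale, `*`)
    SummarizedExperiment::assay(x, "counts") <- cts
    metadata(x)$normalized <- TRUE
    x
}

## shared helper: drop rows flagged by `remove`, returning (table, removed)
.dropRows <- function(x, remove) {
    list(table = x[!remove, ], removed = sum(remove))
}

#' Remove orphan barcodes
#'
#' Orphans are barcodes with no counts in either injection-site sample
#' (dMEC or vMEC): target-area counts without a detectable soma are
#' presumed artifacts.
#'
#' @param x a normalized \linkS4class{BarcodeExperiment}
#' @return list with `table` (filtered) and `removed` (row count).
#' @export
dropOrphans <- function(x) {
    .dropRows(x, .injSum(x) == 0)
}

#' Zero counts at or below the negative-control floor
#'
#' Computes the given percentile (default 90th) of all barcode counts in
#' the negative-control samples — zeros included, nearest-rank
#' convention — and sets every count less than or equal to that
#' threshold, in every sample, to zero. In the original data this floor
#' was 1, i.e. all counts of 1 were set to 0.
#'
#' @param x a normalized \linkS4class{BarcodeExperiment} with >= 1
#'   control sample
#' @param controlPercentile percentile of the control counts, in (0, 100]
#' @return list with `table` and `threshold`.
#' @export
applyControlFloor <- function(x, controlPercentile = 90) {
    stopifnot(controlPercentile > 0, controlPercentile <= 100)
    ctrl <- .ctrlCols(x)
    if (!length(ctrl))
        stop("no control sample present")
    ctrlCounts <- as.vector(bcCounts(x)[, ctrl, drop = FALSE])
    threshold <- if (!length(ctrlCounts)) 0 else {
        sorted <- sort(ctrlCounts)
        sorted[ceiling(controlPercentile / 100 * length(sorted))]
    }
    cts <- bcCounts(x)
    cts[cts <= threshold] <- 0
    SummarizedExperiment::assay(x, "counts") <- cts
    list(table = x, threshold = threshold)
}

#' Remove barcodes with a target count exceeding the injection site
#'
#' Barcodes whose maximum count over the five target areas exceeds
#' (strictly) the injection-site count arise from incomplete dissection
#' of the injection site or pipette-track spillover, and are removed.
#' The injection-site count is the sum of the dMEC and vMEC samples.
#'
#' @inheritParams dropOrphans
#' @return list with `table` and `removed`.
#' @export
dropTargetExceedsInjection <- function(x) {
    tmax <- apply(bcCounts(x)[, .targetCols(x), drop = FALSE], 1L, max)
    .dropRows(x, tmax > .injSum(x))
}

#' Remove barcodes absent from all telencephalic target areas
#'
#' Barcodes with no counts in isocortex, CNU or Olf/Ctxsp carry no
#' information about telencephalic collateralization; this also removes
#' barcodes detected only in the hippocampus.
#'
#' @inheritParams dropOrphans
#' @return list with `table` and `removed`.
#' @export
dropNonTelencephalic <- function(x) {
    telSum <- rowSums(bcCounts(x)[, .telCols(x), drop = FALSE])
    .dropRows(x, telSum == 0)
}

#' Remove barcodes with low injection-site counts
#'
#' Excludes barcodes with an injection-site count (dMEC + vMEC) below
#' the threshold (default 400), guarding against incomplete barcode
#' transport from weakly expressing somata and PCR/polymerase errors.
#'
#' @inheritParams dropOrphans
#' @param minInjectionCount minimum injection-site count kept
#' @return list with `table` and `removed`.
#' @export
dropLowInjection <- function(x, minInjectionCount = 400) {
    stopifnot(minInjectionCount > 0)
    .dropRows(x, .injSum(x) < minInjectionCount)
}

#' Remove barcodes with low counts in all target areas
#'
#' Excludes barcodes whose maximum count across the five target areas is
#' below the threshold (default 10), to limit false-positive projection
#' calls.
#'
#' @inheritParams dropOrphans
#' @param minTargetCount minimum of the per-row maximum target count kept
#' @return list with `table` and `removed`.
#' @export
dropLowTargets <- function(x, minTargetCount = 10) {
    stopifnot(minTargetCount > 0)
    tmax <- apply(bcCounts(x)[, .targetCols(x), drop = FALSE], 1L, max)
    .dropRows(x, tmax < minTargetCount)
}

#' Run the full barcode filtering pipeline
#'
#' Applies, in order: spike-in normalization, orphan removal, the
#' negative-control floor, removal of barcodes whose target counts
#' exceed the injection site, removal of barcodes absent from all
#' telencephalic areas, the minimum injection-site count (default 400)
#' and the minimum target count (default 10). Returns the filtered
#' table together with a per-stage \linkS4class{FilterReport}.
#'
#' @param x a raw (or already normalized) \linkS4class{BarcodeExperiment}
#' @param controlPercentile percentile for [applyControlFloor()]
#' @param minInjectionCount threshold for [dropLowInjection()]
#' @param minTargetCount threshold for [dropLowTargets()]
#' @return list with `table` (filtered \linkS4class{BarcodeExperiment})
#'   and `report` (\linkS4class{FilterReport}).
#' @examples
#' res <- runFilterPipeline(exampleBarcodeExperiment())
#' res$report
#' @export
runFilterPipeline <- function(x, controlPercentile = 90,
                              minInjectionCount = 400, minTargetCount = 10) {
    stages <- list()
    note <- function(name, nIn, removed, threshold = NA_real_) {
        stages[[length(stages) + 1L]] <<- data.frame(
            stage = name, n_in = nIn, n_removed = removed,
            threshold = threshold)
    }
    if (!isNormalized(x)) {
        x <- normalizeBySpikein(x)
        note("normalize_by_spikein", nrow(x), 0L)
    }
    st <- dropOrphans(x)
    note("drop_orphans", nrow(x), st$removed)
    x <- st$table

    fl <- applyControlFloor(x, controlPercentile)
    note("control_floor", nrow(x), 0L, fl$threshold)
    x <- fl$table

    st <- dropTargetExceedsInjection(x)
    note("drop_target_exceeds_injection", nrow(x), st$removed)
    x <- st$table

    st <- dropNonTelencephalic(x)
    note("drop_non_telencephalic", nrow(x), st$removed)
    x <- st$table

    st <- dropLowInjection(x, minInjectionCount)
    note("drop_low_injection", nrow(x), st$removed, minInjectionCount)
    x <- st$table

    st <- dropLowTargets(x, minTargetCount)
    note("drop_low_targets", nrow(x), st$removed, minTargetCount)
    x <- st$table

    list(table = x,
         report = new("FilterReport", stages = do.call(rbind, stages)))
}
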