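#' Co-projection proportion for one telencephalic division
#'
#' Of the barcodes detected (count > 0 after filtering) in a given
#' telencephalic division, the percentage that are also detected in the
#' hippocampus (dHip + vHip > 0):
#' 100 x (barcodes in both division and hippocampus) / (barcodes in
#' division). A barcode can contribute to the proportion of every
#' division it is detected in.
#'
#' @param x a filtered \linkS4class{BarcodeExperiment}
#' @param division name of a telencephalic target sample (e.g.
#'   `"isocortex"`); must be one of the samples with role
#'   `"telencephalic"`
#' @return list with `division`, `nDivision`, `nBoth`, `percent`
#'   (NA with a warning when no barcode is detected in the division).
#' @export
coprojectionProportion <- function(x, division) {
    telNames <- colnames(x)[.telCols(x)]
    if (!division %in% telNames)
        stop("division must be one of: ", paste(telNames, collapse = ", "))
    cts <- bcCounts(x)
    inDiv <- cts[, division] > 0
    hipPos <- rowSums(cts[, .hipCols(x), drop = FALSE]) > 0
    nDiv <- sum(inDiv)
    nBoth <- sum(inDiv & hipPos)
    pct <- if (nDiv > 0) 100 * nBoth / nDiv else {
        warning("no barcode detected in division '", division,
                "'; proportion undefined")
        NA_real_
    }
    list(division = division, nDivision = nDiv, nBoth = nBoth, percent = pct)
}

#' Co-projection summary over all telencephalic divisions
#'
#' @param x a filtered \linkS4class{BarcodeExperiment}
#' @return data.frame with one row per telencephalic division and
#'   columns `division`, `n_division`, `n_both`, `percent`.
#' @examples
#' res <- runFilterPipeline(exampleBarcodeExperiment())
#' coprojectionSummary(res$table)
#' @export
coprojectionSummary <- function(x) {
    telNames <- colnames(x)[.telCols(x)]
    rows <- lapply(telNames, function(d)
        suppressWarnings(coprojectionProportion(x, d)))
    data.frame(division = telNames,
               n_division = vapply(rows, `[[`, 0L, "nDivision"),
               n_both = vapply(rows, `[[`, 0L, "nBoth"),
               percent = vapply(rows, `[[`, 0, "percent"))
}

#' Classify barcode origin as dorsal or ventral MEC
#'
#' A barcode originates from dorsal MEC when its dMEC count exceeds its
#' vMEC count, from ventral MEC in the opposite case; equal counts are a
#' tie and are reported separately.
#'
#' @param x a \linkS4class{BarcodeExperiment}
#' @return factor with levels `dorsal`, `ventral`, `tie`, one per barcode.
#' @export
classifyOrigin <- function(x) {
    cts <- bcCounts(x)
    dm <- cts[, .posCol(x, "injection", "dorsal")]
    vm <- cts[, .posCol(x, "injection", "ventral")]
    factor(ifelse(dm > vm, "dorsal", ifelse(vm > dm, "ventral", "tie")),
           levels = c("dorsal", "ventral", "tie"))
}

#' Normalized hippocampal projection strength
#'
#' For each barcode with any hippocampal counts, the percentage of its
#' hippocampal signal in dHip and vHip:
#' strength_dHip = counts_dHip / (counts_dHip + counts_vHip) x 100, and
#' likewise for vHip; the pair sums to 100. Barcodes with no hippocampal
#' counts are returned as NA and are excluded from topography displays.
#'
#' @param x a \linkS4class{BarcodeExperiment}
#' @return matrix, barcodes x c(`pctDHip`, `pctVHip`).
#' @export
hipProjectionStrength <- function(x) {
    cts <- bcCounts(x)
    dh <- cts[, .posCol(x, "hippocampal", "dorsal")]
    vh <- cts[, .posCol(x, "hippocampal", "ventral")]
    tot <- dh + vh
    out <- cbind(pctDHip = ifelse(tot > 0, 100 * dh / tot, NA_real_),
                 pctVHip = ifelse(tot > 0, 100 * vh / tot, NA_real_))
    rownames(out) <- rownames(x)
    out
}

#' Dorso-ventral topography matrix
#'
#' Rows are hippocampus-projecting barcodes (dHip + vHip > 0), columns
#' the normalized projection strengths to dHip and vHip (each row sums
#' to 100), annotated with the dorsal/ventral origin class. Rows are
#' grouped by origin (dorsal first), and within each group sorted by
#' maximum projection site (dHip-dominated rows first) and then by the
#' strength of that maximal site, descending — the ordering used for
#' heatmap display. Tie-origin barcodes are excluded and counted in
#' `nTies`.
#'
#' @param x a filtered \linkS4class{BarcodeExperiment}
#' @return list with `strengths` (matrix, rows sum to 100), `origin`
#'   (factor aligned to rows), `nTies` (excluded tie-origin rows).
#'   Empty, with a warning, when no barcode projects to the hippocampus.
#' @export
topographyMatrix <- function(x) {
    strength <- hipProjectionStrength(x)
    origin <- classifyOrigin(x)
    keep <- !is.na(strength[, 1L])
    if (!any(keep))
        warning("no hippocampus-projecting barcodes; empty topography matrix")
    nTies <- sum(keep & origin == "tie")
    keep <- keep & origin != "tie"
    strength <- strength[keep, , drop = FALSE]
    origin <- droplevels(origin[keep], exclude = "tie")
    grp <- as.integer(factor(origin, levels = c("dorsal", "ventral")))
    dhipMax <- strength[, "pctDHip"] >= 50
    key <- ifelse(dhipMax, strength[, "pctDHip"], -strength[, "pctVHip"])
    ord <- order(grp, -key)
    list(strengths = strength[ord, , drop = FALSE], origin = origin[ord],
         nTies = nTies)
}

#' Percentage of barcodes with counts in negative-control areas
#'
#' Computed after spike-in normalization but before the control floor,
#' this is the contamination level the negative controls report: the
#' percentage of barcodes with any count > 0 in a control sample (about
#' 1% in the original data).
#'
#' @param x a normalized, pre-floor \linkS4class{BarcodeExperiment}
#' @return percentage in [0, 100]; NA with a warning for an empty table.
#' @export
controlContamination <- function(x) {
    if (!nrow(x)) {
        warning("empty table; contamination undefined")
        return(NA_real_)
    }
    ctrl <- bcCounts(x)[, .ctrlCols(x), drop = FALSE]
    100 * sum(rowSums(ctrl > 0) > 0) / nrow(x)
}
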