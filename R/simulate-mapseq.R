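#' Parameters for the synthetic MAPseq generator
#'
#' Bundles and validates the knobs of [simulateMapseq()]. The defaults
#' describe the emulated experiment: a barcode library of diversity 2e6
#' injected into deep MEC, neurons projecting to up to three
#' telencephalic divisions, a high probability (0.99) that a
#' telencephalon-projecting neuron also sends a collateral to the
#' hippocampus, a strong but imperfect dorso-ventral topography (0.9),
#' overdispersed negative-binomial counts, sporadic contamination at the
#' ~1% level seen in negative controls, and a small orphan-barcode rate.
#'
#' @param nNeurons number of infected neurons
#' @param librarySize barcode library diversity N
#' @param collateralProb probability a telencephalon-projecting neuron
#'   also projects to the hippocampus
#' @param divisionProbs per-division projection probabilities (isocortex,
#'   CNU, Olf/Ctxsp); each neuron is conditioned to project to at least
#'   one division
#' @param dvGradient probability that a dorsal-origin neuron's
#'   hippocampal counts favour dHip (and a ventral-origin neuron's
#'   favour vHip)
#' @param meanInjectionCount expected soma-side (injection) count
#' @param meanTargetCount expected count per projected-to target area
#' @param nbDispersion negative-binomial size (dispersion) parameter
#' @param spikeinCounts named per-sample spike-in totals for the eight
#'   samples (dMEC, vMEC, isocortex, CNU, OlfCtxsp, dHip, vHip, control)
#' @param contaminationRate probability that a non-projected target or
#'   control area receives a spurious count of 1
#' @param orphanRate probability that a neuron's injection-site counts
#'   are zeroed (orphan barcode)
#' @param seed integer seed
#' @return validated list of class `MapseqSimParams`.
#' @export
mapseqSimParams <- function(nNeurons,
                            librarySize = 2e6,
                            collateralProb = 0.99,
                            divisionProbs = c(isocortex = 0.5, CNU = 0.5,
                                              OlfCtxsp = 0.4),
                            dvGradient = 0.9,
                            meanInjectionCount = 5000,
                            meanTargetCount = 100,
                            nbDispersion = 2,
                            spikeinCounts = c(dMEC = 1200, vMEC = 1000,
                                              isocortex = 900, CNU = 1100,
                                              OlfCtxsp = 800, dHip = 1000,
                                              vHip = 950, control = 1050),
                            contaminationRate = 0.01,
                            orphanRate = 0.02,
                            seed = 1L) {
    p <- list(nNeurons = nNeurons, librarySize = librarySize,
              collateralProb = collateralProb, divisionProbs = divisionProbs,
              dvGradient = dvGradient,
              meanInjectionCount = meanInjectionCount,
              meanTargetCount = meanTargetCount,
              nbDispersion = nbDispersion, spikeinCounts = spikeinCounts,
              contaminationRate = contaminationRate, orphanRate = orphanRate,
              seed = as.integer(seed))
    probs <- c(p$collateralProb, p$divisionProbs, p$dvGradient,
               p$contaminationRate, p$orphanRate)
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
        stop("all probabilities must lie in [0, 1]")
    if (length(p$divisionProbs) != 3L)
        stop("divisionProbs must give one probability per telencephalic division")
    if (!is.finite(p$nNeurons) || p$nNeurons < 1)
        stop("nNeurons must be a positive count")
    if (!is.finite(p$librarySize) || p$librarySize < 1)
        stop("librarySize must be a positive count")
    if (p$meanInjectionCount <= 0 || p$meanTargetCount <= 0)
        stop("mean counts must be positive")
    if (p$nbDispersion <= 0)
        stop("nbDispersion must be positive")
    if (length(p$spikeinCounts) != 8L || any(p$spikeinCounts <= 0))
        stop("spikeinCounts must give a positive total for all eight samples")
    class(p) <- "MapseqSimParams"
    p
}

#' Generate a synthetic barcode count table with ground truth
#'
#' Simulates the barcode readout of a projection-mapping experiment on
#' deep-MEC neurons. Each neuron gets a dorsal or ventral origin, a set
#' of telencephalic target divisions (at least one), a hippocampal
#' collateral with probability `collateralProb`, and a barcode drawn
#' with replacement from a library of size `librarySize` so barcode
#' collisions occur at the analytic birthday-problem rate; neurons
#' sharing a barcode are merged in the observed table. Counts in
#' projected-to areas are 1 plus a negative-binomial draw; the
#' dorso-ventral topography is imposed by construction (the favoured
#' hippocampal side strictly exceeds the other, as does the origin-side
#' injection count), sample-specific capture is emulated by scaling raw
#' counts to each sample's spike-in total, contamination adds sporadic
#' raw counts of 1 to non-projected areas, and orphans have their
#' injection counts zeroed.
#'
#' @param params a [mapseqSimParams()] object
#' @return list with `table` (raw \linkS4class{BarcodeExperiment},
#'   one row per distinct observed barcode) and `truth` (per-neuron
#'   `DataFrame`: origin, division flags, collateral, barcode label,
#'   shared flag).
#' @examples
#' sim <- simulateMapseq(mapseqSimParams(nNeurons = 200, seed = 7))
#' sim$table
#' @export
simulateMapseq <- function(params) {
    stopifnot(inherits(params, "MapseqSimParams"))
    set.seed(params$seed)
    n <- as.integer(params$nNeurons)
    size <- params$nbDispersion
    rnb <- function(m, mu) stats::rnbinom(m, size = size, mu = mu)

    origin <- sample(c("dorsal", "ventral"), n, replace = TRUE)
    div <- vapply(params$divisionProbs,
                  function(p) stats::runif(n) < p, logical(n))
    div <- matrix(div, nrow = n,
                  dimnames = list(NULL, names(params$divisionProbs)))
    none <- which(rowSums(div) == 0L)
    while (length(none)) {          # condition on >= 1 telencephalic target
        div[none, ] <- vapply(params$divisionProbs,
                              function(p) stats::runif(length(none)) < p,
                              logical(length(none)))
        none <- none[rowSums(div[none, , drop = FALSE]) == 0L]
    }
    collateral <- stats::runif(n) < params$collateralProb
    barcode <- sample.int(params$librarySize, n, replace = TRUE)

    ## injection counts: origin side strictly exceeds the other
    minorInj <- rnb(n, 0.05 * params$meanInjectionCount)
    majorInj <- minorInj + 1 + rnb(n, params$meanInjectionCount)
    dMEC <- ifelse(origin == "dorsal", majorInj, minorInj)
    vMEC <- ifelse(origin == "dorsal", minorInj, majorInj)

    ## telencephalic counts: >= 1 in every projected-to division
    tel <- matrix(0, n, 3L, dimnames = list(NULL, colnames(div)))
    for (j in seq_len(3L)) {
        idx <- div[, j]
        tel[idx, j] <- 1 + rnb(sum(idx), params$meanTargetCount)
    }

    ## hippocampal counts: favoured side strictly exceeds the other
    favDHip <- ifelse(origin == "dorsal",
                      stats::runif(n) < params$dvGradient,
                      stats::runif(n) >= params$dvGradient)
    minorHip <- rnb(n, 0.25 * params$meanTargetCount)
    majorHip <- minorHip + 1 + rnb(n, params$meanTargetCount)
    dHip <- ifelse(collateral, ifelse(favDHip, majorHip, minorHip), 0)
    vHip <- ifelse(collateral, ifelse(favDHip, minorHip, majorHip), 0)

    counts <- cbind(dMEC = dMEC, vMEC = vMEC, tel, dHip = dHip, vHip = vHip,
                    control = 0)

    ## sporadic contamination: counts of 1 in non-projected target/control
    contam <- 3:8                   # target + control columns
    zero <- counts[, contam] == 0
    hit <- zero & matrix(stats::runif(n * length(contam)) <
                             params$contaminationRate,
                         n, length(contam))
    counts[, contam][hit] <- 1

    ## orphan barcodes: injection counts zeroed
    orphan <- stats::runif(n) < params$orphanRate
    counts[orphan, c("dMEC", "vMEC")] <- 0

    ## emulate per-sample capture efficiency tied to the spike-in totals
    spikein <- params$spikeinCounts
    scale <- spikein / max(spikein)
    raw <- counts
    for (j in seq_len(8L))
        raw[, j] <- ceiling(counts[, j] * scale[j])

    ## merge neurons sharing a barcode into one observed row
    bcLab <- sprintf("BC%07d", barcode)
    obs <- rowsum(raw, group = bcLab)
    shared <- duplicated(barcode) | duplicated(barcode, fromLast = TRUE)

    tbl <- BarcodeExperiment(
        obs,
        role = c("injection", "injection", "telencephalic", "telencephalic",
                 "telencephalic", "hippocampal", "hippocampal", "control"),
        spikein = unname(spikein),
        position = c("dorsal", "ventral", NA, NA, NA, "dorsal", "ventral", NA))
    truth <- S4Vectors::DataFrame(
        origin = origin,
        isocortex = div[, 1L], CNU = div[, 2L], OlfCtxsp = div[, 3L],
        collateral = collateral, barcode = bcLab, shared = shared,
        orphan = orphan)
    list(table = tbl, truth = truth)
}
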