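## centered running-mean smoother with edge replication; k in samples
.runMean <- function(v, k) {
    k <- max(1L, as.integer(k))
    if (k == 1L)
        return(v)
    half <- k %/% 2L
    padded <- c(rep(v[1L], half), v, rep(v[length(v)], k - 1L - half))
    cs <- cumsum(padded)
    (cs[k:length(padded)] - c(0, cs[seq_len(length(padded) - k)])) / k
}

#' Detect action potentials in a voltage trace
#'
#' Spike onsets are the first crossings of dV/dt above `dvdtThresh`
#' (default 20 V/s, the conventional AP-threshold criterion). The
#' derivative is a central difference on a centred running-mean-smoothed
#' trace so recording noise does not trigger, and a candidate onset only
#' counts as a spike if the trace rises at least `minAmp` above the
#' onset voltage within the following 5 ms. Each onset is paired with
#' the following voltage peak; peaks closer than 1 ms to the previous
#' one are discarded.
#'
#' @param trace voltage trace, mV
#' @param samplingRate Hz
#' @param dvdtThresh threshold on dV/dt, V/s
#' @param smoothMs smoothing window for the derivative, ms
#' @param minAmp minimum rise above the onset voltage for a real spike,
#'   mV
#' @return list with `onsetIdx` and `peakIdx` (sample indices).
#' @export
findSpikes <- function(trace, samplingRate, dvdtThresh = 20, smoothMs = 0.2,
                       minAmp = 20) {
    dt <- 1 / samplingRate
    w <- max(1L, round(smoothMs / 1000 / dt))
    vs <- .runMean(trace, w)
    h <- max(1L, w %/% 2L)
    n <- length(vs)
    dvdt <- numeric(n)
    idx <- (h + 1L):(n - h)
    dvdt[idx] <- (vs[idx + h] - vs[idx - h]) / (2 * h * dt) / 1000  # V/s
    above <- dvdt >= dvdtThresh
    starts <- which(above & !c(FALSE, above[-n]))
    if (!length(starts))
        return(list(onsetIdx = integer(0), peakIdx = integer(0)))
    span <- max(1L, round(0.005 / dt))     # peak search window: 5 ms
    peaks <- vapply(starts, function(i) {
        j <- i:min(length(trace), i + span)
        j[which.max(trace[j])]
    }, integer(1))
    real <- trace[peaks] - vs[starts] >= minAmp
    starts <- starts[real]
    peaks <- peaks[real]
    if (!length(starts))
        return(list(onsetIdx = integer(0), peakIdx = integer(0)))
    keep <- c(TRUE, diff(peaks) > round(0.001 / dt))
    list(onsetIdx = starts[keep], peakIdx = peaks[keep])
}

#' Passive membrane properties from the current-step family
#'
#' RMP is the mean pre-step baseline voltage over all sweeps. Input
#' resistance is the steady-state deflection divided by the injected
#' current on the largest subthreshold depolarizing step (steady state =
#' mean over the last 20% of the step; sweeps with spikes are skipped).
#' The sag ratio is the steady-state deflection over the peak deflection
#' on the largest hyperpolarizing step, both measured from baseline,
#' with the peak taken on a 5-ms smoothed trace.
#'
#' @param sweeps a \linkS4class{SweepSet}
#' @return list with `rmp` (mV), `rin` (MOhm; NA if every depolarizing
#'   step spikes), `sagRatio` (NA without a hyperpolarizing step).
#' @export
extractPassive <- function(sweeps) {
    fs <- sweeps@samplingRate
    dt <- 1 / fs
    iBase <- seq_len(round(sweeps@stepStart / dt))
    iStep <- round(sweeps@stepStart / dt) + seq_len(round(sweeps@stepDur / dt))
    iSS <- iStep[seq.int(floor(0.8 * length(iStep)) + 1L, length(iStep))]
    tr <- sweeps@stepTraces
    rmp <- mean(tr[iBase, ])

    rin <- NA_real_
    depol <- which(sweeps@stepCurrents > 0)
    for (j in depol[order(-sweeps@stepCurrents[depol])]) {
        if (length(findSpikes(tr[iStep, j], fs)$peakIdx))
            next
        dss <- mean(tr[iSS, j]) - mean(tr[iBase, j])
        rin <- dss / sweeps@stepCurrents[j] * 1000
        break
    }

    sag <- NA_real_
    hyper <- which(sweeps@stepCurrents < 0)
    if (length(hyper)) {
        j <- hyper[which.min(sweeps@stepCurrents[hyper])]
        base <- mean(tr[iBase, j])
        dss <- mean(tr[iSS, j]) - base
        k <- round(0.005 / dt)
        sm <- .runMean(tr[iStep, j], k)
        ## drop the edge half-windows, where the centred mean degenerates
        ## to nearly raw samples and a noise outlier can pose as the trough
        inner <- sm[min(k, length(sm)):max(1L, length(sm) - k)]
        dmin <- min(inner) - base
        sag <- dss / dmin
    }
    list(rmp = rmp, rin = rin, sagRatio = sag)
}

#' AP features from the depolarizing current ramp
#'
#' From the first action potential during the ramp: the AP threshold is
#' the voltage at the first dV/dt >= 20 V/s crossing before the peak;
#' the rheobase is the ramp current at that crossing; the AHP is the
#' threshold minus the most negative voltage between the peak and the
#' next spike (or +100 ms); the half-width is the AP width at half its
#' spike amplitude (peak minus threshold), with linear interpolation at
#' the crossings.
#'
#' @param sweeps a \linkS4class{SweepSet}
#' @return list with `rheobase` (pA), `rheobaseCensored` (TRUE when no
#'   spike occurred, i.e. rheobase exceeds the ramp maximum),
#'   `apThreshold` (mV), `ahp` (mV), `halfWidth` (ms).
#' @export
extractApFeatures <- function(sweeps) {
    fs <- sweeps@samplingRate
    dt <- 1 / fs
    v <- sweeps@rampTrace
    sp <- findSpikes(v, fs)
    if (!length(sp$peakIdx))
        return(list(rheobase = NA_real_, rheobaseCensored = TRUE,
                    apThreshold = NA_real_, ahp = NA_real_,
                    halfWidth = NA_real_))
    i0 <- sp$onsetIdx[1L]
    p0 <- sp$peakIdx[1L]
    vs <- .runMean(v, round(0.0002 / dt))
    thr <- vs[i0]
    rheobase <- sweeps@rampSlope * ((i0 - 1L) * dt - sweeps@rampStart)

    winEnd <- if (length(sp$onsetIdx) > 1L) sp$onsetIdx[2L] else
        min(length(v), p0 + round(0.1 / dt))
    trough <- min(.runMean(v[p0:winEnd], round(0.001 / dt)))
    ahp <- thr - trough

    peakV <- v[p0]
    half <- (peakV + thr) / 2
    iUp <- p0
    while (iUp > 1L && v[iUp - 1L] >= half) iUp <- iUp - 1L
    tUp <- (iUp - 1L) * dt
    if (iUp > 1L && v[iUp] != v[iUp - 1L])
        tUp <- tUp - dt * (v[iUp] - half) / (v[iUp] - v[iUp - 1L])
    iDn <- p0
    while (iDn < length(v) && v[iDn + 1L] >= half) iDn <- iDn + 1L
    tDn <- (iDn - 1L) * dt
    if (iDn < length(v) && v[iDn] != v[iDn + 1L])
        tDn <- tDn + dt * (v[iDn] - half) / (v[iDn] - v[iDn + 1L])
    list(rheobase = rheobase, rheobaseCensored = FALSE, apThreshold = thr,
         ahp = ahp, halfWidth = (tDn - tUp) * 1000)
}

#' Firing frequencies from the 1-s 200-pA step
#'
#' The mean firing frequency is the spike count over the 1-s step; the
#' maximum firing frequency is the reciprocal of the first inter-spike
#' interval and the base frequency the reciprocal of the last. With
#' fewer than two spikes the interval-based measures are NA.
#'
#' @param sweeps a \linkS4class{SweepSet}
#' @return list with `firingFreq`, `maxFreq`, `baseFreq` (Hz).
#' @export
firingFrequencies <- function(sweeps) {
    fs <- sweeps@samplingRate
    dt <- 1 / fs
    sp <- findSpikes(sweeps@step200Trace, fs)
    tSpk <- (sp$peakIdx - 1L) * dt
    tSpk <- tSpk[tSpk >= sweeps@stepStart &
                 tSpk <= sweeps@stepStart + sweeps@stepDur]
    n <- length(tSpk)
    if (n < 2L)
        return(list(firingFreq = n / sweeps@stepDur, maxFreq = NA_real_,
                    baseFreq = NA_real_))
    isi <- diff(tSpk)
    list(firingFreq = n / sweeps@stepDur,
         maxFreq = 1 / isi[1L],
         baseFreq = 1 / isi[n - 1L])
}

#' Extract the full intrinsic-property FeatureSet from a SweepSet
#'
#' Combines [extractPassive()], [extractApFeatures()] and
#' [firingFrequencies()] and carries over the bridge balance.
#'
#' @param sweeps a \linkS4class{SweepSet}
#' @return A \linkS4class{FeatureSet}.
#' @export
extractFeatures <- function(sweeps) {
    pas <- extractPassive(sweeps)
    ap <- extractApFeatures(sweeps)
    ff <- firingFrequencies(sweeps)
    new("FeatureSet",
        rmp = pas$rmp, rin = pas$rin, sagRatio = pas$sagRatio,
        rheobase = ap$rheobase, rheobaseCensored = ap$rheobaseCensored,
        apThreshold = ap$apThreshold, ahp = ap$ahp,
        halfWidth = ap$halfWidth,
        firingFreq = ff$firingFreq, maxFreq = ff$maxFreq,
        baseFreq = ff$baseFreq,
        bridge = sweeps@bridgeBalance)
}

#' Recording quality-control gate
#'
#' A cell is excluded when its resting membrane potential is less
#' negative than -50 mV or its bridge balance exceeds 40 MOhm (both
#' strict inequalities).
#'
#' @param features a \linkS4class{FeatureSet}
#' @return TRUE when the recording passes QC.
#' @export
qcGate <- function(features) {
    !(features@rmp > -50 || features@bridge > 40)
}

#' Hierarchical cell-type classification from intrinsic properties
#'
#' Applies the criterion boxes, with the criteria evaluated in the
#' stated descending order (maximum firing frequency, AHP, AP
#' half-width, sag ratio):
#' pyramidal — max freq < 50 Hz, AHP < 10 mV, half-width >= 0.7 ms,
#' sag <= 0.9; fast-spiking interneuron — max freq >= 100 Hz,
#' AHP >= 12 mV, half-width < 0.5 ms, sag > 0.9; non-fast-spiking
#' interneuron — max freq 50-100 Hz, AHP >= 12 mV, half-width
#' 0.5-0.9 ms, sag > 0.9. The three frequency bands are disjoint, so
#' the first criterion selects a unique candidate class; with
#' `requireAll = TRUE` (default) the remaining criteria must also hold,
#' otherwise the cell is `unclassified`. Cells failing [qcGate()] are
#' `excluded_qc`.
#'
#' @param features a \linkS4class{FeatureSet}
#' @param requireAll require all four criteria of the candidate class
#'   (when FALSE the frequency band alone decides)
#' @return one of `"pyramidal"`, `"FS_interneuron"`, `"NFS_interneuron"`,
#'   `"unclassified"`, `"excluded_qc"`.
#' @examples
#' classifyCell(extractFeatures(simulateSweeps("FS", seed = 1)))
#' @export
classifyCell <- function(features, requireAll = TRUE) {
    if (!qcGate(features))
        return("excluded_qc")
    f <- features
    if (anyNA(c(f@maxFreq, f@ahp, f@halfWidth, f@sagRatio)))
        return("unclassified")
    if (f@maxFreq < 50) {
        ok <- f@ahp < 10 && f@halfWidth >= 0.7 && f@sagRatio <= 0.9
        cls <- "pyramidal"
    } else if (f@maxFreq >= 100) {
        ok <- f@ahp >= 12 && f@halfWidth < 0.5 && f@sagRatio > 0.9
        cls <- "FS_interneuron"
    } else {
        ok <- f@ahp >= 12 && f@halfWidth >= 0.5 && f@halfWidth <= 0.9 &&
            f@sagRatio > 0.9
        cls <- "NFS_interneuron"
    }
    if (requireAll && !ok)
        return("unclassified")
    cls
}
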