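#' Quantify an optogenetically evoked PSP from repeated trials
#'
#' Per trial, the baseline is the mean membrane potential over the 10 ms
#' before the stimulus and the response peak is taken within 50 ms after
#' it. The peak time is estimated by two-fold cross-fitting — the trials
#' are split into halves and each half is measured at the peak time of
#' the other half's mean trace — so that under the null hypothesis of no
#' response the per-trial peak values are unbiased and the
#' responsiveness test keeps its nominal type-I error; a peak searched
#' on the same trials it is measured on is systematically biased away
#' from baseline by noise. Responsiveness is a two-tailed paired Student's t-test of
#' the per-trial peaks against the per-trial baselines; the amplitude is
#' the mean peak-minus-baseline deflection (signed). The onset latency
#' per trial is the first sustained crossing of baseline +/- 2 SD of the
#' baseline toward the peak; its trial-to-trial SD (the latency jitter,
#' the monosynapticity measure) is reported for responses exceeding
#' 1 mV. Polarity is depolarizing or hyperpolarizing by the sign of the
#' amplitude, or biphasic when the mean trace has both a significant
#' positive and a significant negative excursion.
#'
#' @param trials samples x trials voltage matrix (mV), or the list
#'   returned by [simulatePspTrials()]
#' @param samplingRate Hz (taken from the list input when omitted)
#' @param stimTime stimulus onset within the trial, s
#' @param baselineMs baseline window before the stimulus, ms
#' @param responseMs response window after the stimulus, ms
#' @param alpha significance level of the responsiveness test
#' @return A \linkS4class{PspResult}.
#' @export
pspAnalyze <- function(trials, samplingRate = NULL, stimTime = NULL,
                       baselineMs = 10, responseMs = 50, alpha = 0.05) {
    if (is.list(trials) && !is.null(trials$trials)) {
        samplingRate <- trials$samplingRate
        stimTime <- trials$stimTime
        trials <- trials$trials
    }
    stopifnot(is.matrix(trials), !is.null(samplingRate), !is.null(stimTime))
    nTrials <- ncol(trials)
    if (nTrials < 2L)
        stop("at least 2 trials are required for the responsiveness test")
    dt <- 1 / samplingRate
    iStim <- round(stimTime / dt) + 1L
    iBase <- max(1L, iStim - round(baselineMs / 1000 / dt)):(iStim - 1L)
    iResp <- iStim:min(nrow(trials), iStim + round(responseMs / 1000 / dt))

    sm <- apply(trials, 2L, .runMean, k = round(0.0005 / dt))
    baselines <- colMeans(trials[iBase, , drop = FALSE])
    dev <- sweep(sm, 2L, baselines)

    ## cross-fitted peak time: each half's trials are measured at the peak
    ## time estimated from the mean of the *other* half, so under the null
    ## the peak values are unbiased and the test keeps its nominal level
    halfA <- seq(1L, nTrials, by = 2L)
    halfB <- setdiff(seq_len(nTrials), halfA)
    peakTime <- function(cols) {
        m <- rowMeans(dev[iResp, cols, drop = FALSE])
        iResp[which.max(abs(m))]
    }
    peaks <- numeric(nTrials)
    peaks[halfA] <- dev[peakTime(halfB), halfA]
    peaks[halfB] <- dev[peakTime(halfA), halfB]
    ht <- studentT(peaks)      # paired test of peaks vs baselines
    amplitude <- mean(peaks)

    ## polarity from the mean trace
    m <- rowMeans(dev)
    sB <- stats::sd(m[iBase])
    pkPos <- max(m[iResp])
    pkNeg <- -min(m[iResp])
    gate <- max(4 * sB, 0.25 * max(pkPos, pkNeg))
    polarity <- if (pkPos > gate && pkNeg > gate) "biphasic"
    else if (amplitude >= 0) "depolarizing" else "hyperpolarizing"

    ## per-trial onset latency: first sustained 2-SD crossing toward the peak
    dir <- if (amplitude >= 0) 1 else -1
    sustain <- max(1L, round(0.0003 / dt))
    latencies <- vapply(seq_len(nTrials), function(i) {
        sdB <- stats::sd(trials[iBase, i])
        thr <- 2 * sdB
        x <- dir * dev[iResp, i]
        cross <- which(x > thr)
        for (j in cross) {
            jj <- j:min(length(x), j + sustain - 1L)
            if (all(x[jj] > thr))
                return((iResp[j] - iStim) * dt * 1000)
        }
        NA_real_
    }, numeric(1))
    lat <- latencies[!is.na(latencies)]
    latencySd <- if (abs(amplitude) > 1 && length(lat) >= 2L)
        stats::sd(lat) else NA_real_

    new("PspResult",
        responsive = ht$p.value < alpha,
        pValue = ht$p.value,
        amplitude = amplitude,
        meanLatency = if (length(lat)) mean(lat) else NA_real_,
        latencySd = latencySd,
        polarity = polarity,
        nTrials = as.integer(nTrials))
}
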