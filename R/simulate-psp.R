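#' Generate synthetic optogenetic PSP trials
#'
#' Each trial is a flat membrane potential plus, at the stimulus time
#' plus a Gaussian-jittered latency, an alpha-function deflection
#' (`amp * (t/tau) * exp(1 - t/tau)`, peaking at `amp` after `riseMs`),
#' with additive Gaussian noise. Polarity `"depol"` gives an upward
#' deflection, `"hyperpol"` a downward one, and `"biphasic"` an early
#' depolarizing component followed 8 ms later by a hyperpolarizing one.
#'
#' @param amplitude PSP amplitude magnitude, mV (>= 0)
#' @param latencyMs mean onset latency after the stimulus, ms
#' @param jitterSd trial-to-trial SD of the onset latency, ms (>= 0)
#' @param polarity `"depol"`, `"hyperpol"` or `"biphasic"`
#' @param nTrials number of trials (>= 2)
#' @param noiseSd additive voltage noise, mV
#' @param seed optional integer seed
#' @param samplingRate Hz
#' @param holdingMv holding membrane potential, mV
#' @param stimTime light-pulse onset within the trial, s
#' @param trialDur trial duration, s
#' @param riseMs alpha-function time-to-peak, ms
#' @return list with `trials` (samples x trials voltage matrix, mV),
#'   `samplingRate`, `stimTime` and `truth` (the generator parameters).
#' @examples
#' ps <- simulatePspTrials(2, polarity = "depol", seed = 1)
#' pspAnalyze(ps)
#' @export
simulatePspTrials <- function(amplitude, latencyMs = 3, jitterSd = 0.25,
                              polarity = c("depol", "hyperpol", "biphasic"),
                              nTrials = 10, noiseSd = 0.1, seed = NULL,
                              samplingRate = 20000, holdingMv = -67,
                              stimTime = 0.1, trialDur = 0.25, riseMs = 2) {
    polarity <- match.arg(polarity)
    if (amplitude < 0)
        stop("amplitude is a magnitude and must be non-negative")
    if (jitterSd < 0)
        stop("jitterSd must be non-negative")
    if (nTrials < 2)
        stop("at least 2 trials are required")
    if (!is.null(seed))
        set.seed(seed)
    dt <- 1 / samplingRate
    n <- round(trialDur / dt)
    tt <- (seq_len(n) - 1L) * dt
    alphaK <- function(t0) {
        u <- (tt - t0) / (riseMs / 1000)
        ifelse(u > 0, u * exp(1 - u), 0)
    }
    onsets <- stimTime + (latencyMs + stats::rnorm(nTrials, 0, jitterSd)) / 1000
    trials <- vapply(seq_len(nTrials), function(i) {
        resp <- switch(polarity,
                       depol = amplitude * alphaK(onsets[i]),
                       hyperpol = -amplitude * alphaK(onsets[i]),
                       biphasic = amplitude * alphaK(onsets[i]) -
                           0.8 * amplitude * alphaK(onsets[i] + 0.008))
        holdingMv + resp + stats::rnorm(n, 0, noiseSd)
    }, numeric(n))
    list(trials = trials, samplingRate = samplingRate, stimTime = stimTime,
         truth = list(amplitude = amplitude, latencyMs = latencyMs,
                      jitterSd = jitterSd, polarity = polarity,
                      noiseSd = noiseSd, holdingMv = holdingMv,
                      onsets = onsets))
}
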