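## Per-class generator parameters. Chosen so every extracted feature sits
## inside the corresponding classification criterion box with a margin
## that survives 1 mV of recording noise (see the methods vignette):
##   pyramidal: max freq < 50 Hz, AHP < 10 mV, half-width >= 0.7 ms, sag <= 0.9
##   FS:        max freq >= 100,  AHP >= 12,   half-width < 0.5,     sag > 0.9
##   NFS:       max freq 50-100,  AHP >= 12,   half-width 0.5-0.9,   sag > 0.9
## Times in seconds, voltages mV, resistances MOhm.
.CLASS_PARAMS <- list(
    pyramidal = list(rmp = -68, rin = 150, tau = 0.020, sagTrue = 0.80,
                     thr = -45, apAmp = 80, hw = 0.9, ahp = 6, lat = 0.015,
                     isi1 = 0.028, isiInf = 0.045, thrInc = 1.5, bridge = 15),
    FS = list(rmp = -65, rin = 150, tau = 0.008, sagTrue = 0.98,
              thr = -42, apAmp = 60, hw = 0.35, ahp = 16, lat = 0.002,
              isi1 = 0.006, isiInf = 0.008, thrInc = 0.8, bridge = 12),
    NFS = list(rmp = -62, rin = 200, tau = 0.015, sagTrue = 0.96,
               thr = -44, apAmp = 70, hw = 0.7, ahp = 15, lat = 0.008,
               isi1 = 0.0133, isiInf = 0.018, thrInc = 1.0, bridge = 14))

## Stereotyped AP waveform pasted at threshold crossings: linear rise over
## 0.6*hw to thr+apAmp, then a linear fall to thr-ahp whose duration is set
## so that the half-amplitude crossing (which sits a fraction
## (apAmp/2)/(apAmp+ahp) of the way down the flank) lands at hw exactly.
.apTemplate <- function(p, dt) {
    tr <- 0.6 * p$hw / 1000
    tf <- (p$hw - 0.3 * p$hw) / 1000 * (p$apAmp + p$ahp) / (p$apAmp / 2)
    nr <- max(2L, round(tr / dt))
    nf <- max(2L, round(tf / dt))
    peak <- p$thr + p$apAmp
    c(seq(p$thr, peak, length.out = nr + 1L)[-1L],
      seq(peak, p$thr - p$ahp, length.out = nf + 1L)[-1L])
}

#' Generate synthetic current-clamp sweeps for one cell class
#'
#' Produces the three protocols the intrinsic-property analysis expects
#' — a step family (-40 to +40 pA in 20-pA increments, 1 s), a
#' depolarizing ramp (50 pA/s to 400 pA) and a 1-s 200-pA step — from a
#' reduced membrane model: closed-form RC subthreshold responses with an
#' Ih-like sag component on hyperpolarizing steps, leaky
#' integrate-and-fire threshold crossings on the ramp (with per-spike
#' threshold adaptation), a stereotyped pasted AP waveform, and a
#' deterministic accommodating inter-spike-interval schedule on the
#' 200-pA step. Parameters per class are fixed so that the extracted
#' features fall inside that class's classification criterion box.
#'
#' @param cellClass `"pyramidal"`, `"FS"` or `"NFS"`
#' @param noiseSd additive Gaussian voltage noise, mV
#' @param seed optional integer seed (same seed, same traces)
#' @param samplingRate sampling rate in Hz
#' @return A \linkS4class{SweepSet}; `@groundTruth` carries the
#'   generator parameters.
#' @examples
#' sw <- simulateSweeps("pyramidal", noiseSd = 0, seed = 1)
#' extractFeatures(sw)
#' @export
simulateSweeps <- function(cellClass = c("pyramidal", "FS", "NFS"),
                           noiseSd = 0, seed = NULL, samplingRate = 25000) {
    cellClass <- match.arg(cellClass)
    p <- .CLASS_PARAMS[[cellClass]]
    if (noiseSd < 0)
        stop("noiseSd must be non-negative")
    if (!is.null(seed))
        set.seed(seed)
    dt <- 1 / samplingRate
    stepStart <- 0.2
    stepDur <- 1.0
    tailDur <- 0.3
    k <- p$rin / 1000                      # mV per pA

    nBase <- round(stepStart / dt)
    nStep <- round(stepDur / dt)
    nTail <- round(tailDur / dt)
    tStep <- seq_len(nStep) * dt

    ## ---- step family ----
    currents <- c(-40, -20, 20, 40)
    tauSag <- 0.15
    g <- (1 - exp(-tStep / p$tau)) * exp(-tStep / tauSag)
    gmax <- max(g)
    mkStep <- function(I) {
        dss <- I * k
        d <- dss * (1 - exp(-tStep / p$tau))
        if (I < 0)                          # sag overshoot on hyperpolarization
            d <- d + dss * (1 / p$sagTrue - 1) / gmax * g
        dEnd <- d[nStep]
        c(rep(p$rmp, nBase), p$rmp + d,
          p$rmp + dEnd * exp(-seq_len(nTail) * dt / p$tau))
    }
    stepTraces <- vapply(currents, mkStep, numeric(nBase + nStep + nTail))

    ## ---- ramp: LIF with closed-form RC segments between spikes ----
    rampSlope <- 50                        # pA/s
    rampDur <- 8                           # to 400 pA
    nRamp <- round(rampDur / dt)
    kv <- k * rampSlope                    # mV/s of drive
    ramp <- c(rep(p$rmp, nBase), numeric(nRamp))
    tpl <- .apTemplate(p, dt)
    thrEff <- p$thr
    i1 <- 1L                               # sample index within the ramp
    v0 <- p$rmp
    while (i1 <= nRamp) {
        t1 <- (i1 - 1L) * dt
        C <- v0 - (p$rmp + kv * (t1 - p$tau))
        vAt <- function(t) p$rmp + kv * (t - p$tau) + C * exp(-(t - t1) / p$tau)
        tEnd <- (nRamp - 1L) * dt
        if (vAt(tEnd) < thrEff) {
            idx <- i1:nRamp
            ramp[nBase + idx] <- vAt((idx - 1L) * dt)
            break
        }
        tc <- stats::uniroot(function(t) vAt(t) - thrEff,
                             lower = t1, upper = tEnd, tol = dt / 10)$root
        ic <- min(nRamp, max(i1, floor(tc / dt) + 1L))
        if (ic > i1)
            ramp[nBase + (i1:(ic - 1L))] <- vAt((i1:(ic - 1L) - 1L) * dt)
        nTpl <- min(length(tpl), nRamp - ic + 1L)
        ramp[nBase + ic - 1L + seq_len(nTpl)] <- tpl[seq_len(nTpl)]
        i1 <- ic + nTpl
        v0 <- p$thr - p$ahp
        thrEff <- thrEff + p$thrInc        # spike-frequency adaptation
    }
    rampTrace <- ramp

    ## ---- 1-s 200-pA step: accommodating spike train on a rising backbone ----
    plateau <- p$thr - 1
    nSpk <- 200L
    isis <- p$isiInf - (p$isiInf - p$isi1) * exp(-(seq_len(nSpk) - 1L) / 3)
    spkT <- p$lat + cumsum(c(0, isis))
    spkT <- spkT[spkT < stepDur - length(tpl) * dt]
    v <- numeric(nStep)
    fillRise <- function(from, to, vFrom, target) {
        if (to < from) return(invisible())
        tt <- (seq(from, to) - from + 1L) * dt
        v[from:to] <<- target + (vFrom - target) * exp(-tt / p$tau)
    }
    pos <- 1L
    vCur <- p$rmp
    for (ts in spkT) {
        iSpk <- floor(ts / dt) + 1L
        fillRise(pos, iSpk - 1L, vCur, plateau)
        v[iSpk - 1L + seq_along(tpl)] <- tpl
        pos <- iSpk + length(tpl)
        vCur <- p$thr - p$ahp
    }
    fillRise(pos, nStep, vCur, plateau)
    step200 <- c(rep(p$rmp, nBase), v,
                 p$rmp + (v[nStep] - p$rmp) * exp(-seq_len(nTail) * dt / p$tau))

    if (noiseSd > 0) {
        stepTraces <- stepTraces +
            matrix(stats::rnorm(length(stepTraces), 0, noiseSd),
                   nrow(stepTraces))
        rampTrace <- rampTrace + stats::rnorm(length(rampTrace), 0, noiseSd)
        step200 <- step200 + stats::rnorm(length(step200), 0, noiseSd)
    }

    new("SweepSet",
        samplingRate = samplingRate,
        stepCurrents = currents,
        stepTraces = stepTraces,
        rampTrace = rampTrace,
        rampSlope = rampSlope,
        rampStart = stepStart,
        step200Trace = step200,
        stepStart = stepStart,
        stepDur = stepDur,
        stimTimes = numeric(0),
        bridgeBalance = p$bridge,
        groundTruth = c(p, list(cellClass = cellClass, noiseSd = noiseSd)))
}
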