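# Hand-constructed SweepSets for feature-extraction unit tests.

# Step family with prescribed deflections; piecewise-constant "recordings".
# deflHyper is a function of time-in-step (s) giving the deflection (mV)
# on the -40 pA sweep; the +20 pA sweep gets an RC-like subthreshold rise.
makeStepSweeps <- function(rmp = -70, deflHyper = function(t) -9 + 0 * t,
                           rinMOhm = 100, samplingRate = 25000) {
    dt <- 1 / samplingRate
    nBase <- round(0.2 / dt); nStep <- round(1.0 / dt); nTail <- round(0.1 / dt)
    tStep <- seq_len(nStep) * dt
    hyper <- c(rep(rmp, nBase), rmp + deflHyper(tStep), rep(rmp, nTail))
    dss <- 20 * rinMOhm / 1000
    depol <- c(rep(rmp, nBase), rmp + dss * (1 - exp(-tStep / 0.02)),
               rep(rmp, nTail))
    new("SweepSet", samplingRate = samplingRate,
        stepCurrents = c(-40, 20),
        stepTraces = cbind(hyper, depol),
        rampTrace = rep(rmp, nBase), rampSlope = 50, rampStart = 0.2,
        step200Trace = c(rep(rmp, nBase + nStep + nTail)),
        stepStart = 0.2, stepDur = 1, stimTimes = numeric(0),
        bridgeBalance = 10, groundTruth = list())
}

# Ramp trace that is flat at `rmp` until `spikeAt` seconds, then carries one
# triangular spike: rise riseMs to rmp+amp, symmetric fall back to rmp.
makeRampSweeps <- function(rmp = -70, spikeAt = 2.2, amp = 40, riseMs = 0.5,
                           samplingRate = 25000) {
    dt <- 1 / samplingRate
    n <- round(8.2 / dt)
    v <- rep(rmp, n)
    i0 <- round(spikeAt / dt) + 1L
    nr <- round(riseMs / 1000 / dt)
    tri <- c(seq(rmp, rmp + amp, length.out = nr + 1L)[-1L],
             seq(rmp + amp, rmp, length.out = nr + 1L)[-1L])
    v[i0 + seq_along(tri) - 1L] <- tri
    base <- makeStepSweeps(rmp = rmp, samplingRate = samplingRate)
    base@rampTrace <- v
    base
}

# 200-pA step trace carrying narrow spikes at the given times (s, absolute).
makeTrainSweeps <- function(spikeTimes, rmp = -70, plateau = -55, amp = 60,
                            samplingRate = 25000) {
    dt <- 1 / samplingRate
    nBase <- round(0.2 / dt); nStep <- round(1.0 / dt); nTail <- round(0.1 / dt)
    v <- c(rep(rmp, nBase), rep(plateau, nStep), rep(rmp, nTail))
    nr <- round(0.0003 / dt)
    tri <- c(seq(plateau, plateau + amp, length.out = nr + 1L)[-1L],
             seq(plateau + amp, plateau, length.out = nr + 1L)[-1L])
    for (ts in spikeTimes) {
        i0 <- round(ts / dt) + 1L
        v[i0 + seq_along(tri) - 1L] <- tri
    }
    base <- makeStepSweeps(rmp = rmp, samplingRate = samplingRate)
    base@step200Trace <- v
    base
}

# Bare FeatureSet for classifier-rule tests.
makeFeatures <- function(maxFreq, ahp, halfWidth, sag, rmp = -65,
                         bridge = 20) {
    new("FeatureSet", rmp = rmp, rin = 150, sagRatio = sag, rheobase = 100,
        rheobaseCensored = FALSE, apThreshold = -45, ahp = ahp,
        halfWidth = halfWidth, firingFreq = maxFreq * 0.8, maxFreq = maxFreq,
        baseFreq = maxFreq * 0.7, bridge = bridge)
}
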