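test_that("passive properties follow the deflection definitions", {
    ## ideal RC response, no sag conductance: V_ss = V_min, ratio 1
    sw <- makeStepSweeps(deflHyper = function(t) -9 * (1 - exp(-t / 0.02)))
    p <- extractPassive(sw)
    expect_equal(p$sagRatio, 1, tolerance = 0.01)
    expect_equal(p$rmp, -70, tolerance = 0.1)
    expect_equal(p$rin, 100, tolerance = 1)

    ## steady-state deflection -9 mV, peak deflection -10 mV: sag 0.9
    sw <- makeStepSweeps(deflHyper = function(t) ifelse(t < 0.1, -10, -9))
    expect_equal(extractPassive(sw)$sagRatio, 0.9, tolerance = 0.01)
})

test_that("input resistance is recovered from generated sweeps", {
    f <- extractPassive(simulateSweeps("pyramidal", noiseSd = 0, seed = 1))
    expect_equal(f$rin, 150, tolerance = 2)
    f <- extractPassive(simulateSweeps("NFS", noiseSd = 0, seed = 1))
    expect_equal(f$rin, 200, tolerance = 2)
})

test_that("AP features follow their geometric definitions on a known spike", {
    ## flat ramp trace, one symmetric triangular spike at t = 2.2 s:
    ## ramp current 50 pA/s from 0.2 s -> rheobase 100 pA; 40 mV spike with
    ## 1 ms base -> half-width 0.5 ms; returns to baseline -> AHP ~ 0
    sw <- makeRampSweeps(rmp = -70, spikeAt = 2.2, amp = 40, riseMs = 0.5)
    ap <- extractApFeatures(sw)
    expect_false(ap$rheobaseCensored)
    expect_equal(ap$rheobase, 100, tolerance = 2)
    expect_equal(ap$apThreshold, -70, tolerance = 1)
    expect_equal(ap$halfWidth, 0.5, tolerance = 0.06)
    expect_lt(ap$ahp, 1)
    ## no spike at all: censored rheobase
    ap0 <- extractApFeatures(makeStepSweeps())
    expect_true(ap0$rheobaseCensored)
    expect_true(is.na(ap0$apThreshold))
})

test_that("generated AP threshold is recovered within 1 mV", {
    for (cl in c("pyramidal", "FS", "NFS")) {
        sw <- simulateSweeps(cl, noiseSd = 0, seed = 3)
        ap <- extractApFeatures(sw)
        expect_equal(ap$apThreshold, sw@groundTruth$thr, tolerance = 1)
    }
})

test_that("firing frequencies are spike count and first/last ISI reciprocals", {
    ## 10 evenly spaced spikes, ISI 100 ms: all three measures 10 Hz
    sw <- makeTrainSweeps(spikeTimes = 0.25 + (0:9) * 0.1)
    ff <- firingFrequencies(sw)
    expect_equal(ff$firingFreq, 10)
    expect_equal(ff$maxFreq, 10, tolerance = 0.01)
    expect_equal(ff$baseFreq, 10, tolerance = 0.01)
    ## first ISI 5 ms: maximum frequency 200 Hz
    sw <- makeTrainSweeps(spikeTimes = c(0.25, 0.255, 0.3, 0.4))
    expect_equal(firingFrequencies(sw)$maxFreq, 200, tolerance = 1)
    ## no spikes: zero rate, interval measures undefined
    ff0 <- firingFrequencies(makeTrainSweeps(spikeTimes = numeric(0)))
    expect_equal(ff0$firingFreq, 0)
    expect_true(is.na(ff0$maxFreq) && is.na(ff0$baseFreq))
})

test_that("interval frequencies bracket the mean rate on accommodating trains", {
    for (cl in c("pyramidal", "FS", "NFS")) {
        f <- featureTable(extractFeatures(simulateSweeps(cl, 0, seed = 5)))
        expect_gte(f$maxFreq, f$firingFreq)
        expect_gte(f$firingFreq, f$baseFreq - 1e-9)
    }
})

test_that("QC excludes depolarized or high-bridge recordings, strictly", {
    expect_false(qcGate(makeFeatures(40, 8, 0.8, 0.85, rmp = -45)))
    expect_true(qcGate(makeFeatures(40, 8, 0.8, 0.85, rmp = -67, bridge = 20)))
    expect_true(qcGate(makeFeatures(40, 8, 0.8, 0.85, bridge = 40)))   # = 40: pass
    expect_false(qcGate(makeFeatures(40, 8, 0.8, 0.85, bridge = 40.5)))
    expect_equal(classifyCell(makeFeatures(40, 8, 0.8, 0.85, rmp = -45)),
                 "excluded_qc")
})

test_that("classification criterion boxes assign the published classes", {
    expect_equal(classifyCell(makeFeatures(150, 15, 0.4, 0.95)),
                 "FS_interneuron")
    expect_equal(classifyCell(makeFeatures(40, 8, 0.8, 0.85)), "pyramidal")
    expect_equal(classifyCell(makeFeatures(75, 15, 0.7, 0.95)),
                 "NFS_interneuron")
    ## conflicting secondary criteria: unclassified when all are required,
    ## frequency band decides otherwise
    odd <- makeFeatures(150, 5, 0.8, 0.85)
    expect_equal(classifyCell(odd), "unclassified")
    expect_equal(classifyCell(odd, requireAll = FALSE), "FS_interneuron")
    ## missing features
    nf <- makeFeatures(NA_real_, 8, 0.8, 0.85)
    expect_equal(classifyCell(nf), "unclassified")
})

test_that("noise-free synthetic sweeps close the loop for every class", {
    want <- c(pyramidal = "pyramidal", FS = "FS_interneuron",
              NFS = "NFS_interneuron")
    for (cl in names(want))
        expect_equal(classifyCell(extractFeatures(
            simulateSweeps(cl, noiseSd = 0, seed = 11))), unname(want[cl]))
})

test_that("same seed reproduces identical traces", {
    a <- simulateSweeps("FS", noiseSd = 0.5, seed = 9)
    b <- simulateSweeps("FS", noiseSd = 0.5, seed = 9)
    expect_identical(a@rampTrace, b@rampTrace)
    expect_identical(a@stepTraces, b@stepTraces)
    expect_identical(a@step200Trace, b@step200Trace)
    expect_error(simulateSweeps("granule"), "'arg' should be one of")
})

test_that("a DC offset shifts voltages but not derived properties", {
    sw <- simulateSweeps("pyramidal", noiseSd = 0, seed = 13)
    off <- sw
    off@stepTraces <- sw@stepTraces + 5
    off@rampTrace <- sw@rampTrace + 5
    off@step200Trace <- sw@step200Trace + 5
    f0 <- featureTable(extractFeatures(sw))
    f5 <- featureTable(extractFeatures(off))
    expect_equal(f5$rmp, f0$rmp + 5, tolerance = 1e-6)
    expect_equal(f5$apThreshold, f0$apThreshold + 5, tolerance = 1e-6)
    for (col in c("rin", "sagRatio", "halfWidth", "ahp", "firingFreq",
                  "maxFreq", "baseFreq", "rheobase"))
        expect_equal(f5[[col]], f0[[col]], tolerance = 1e-6, label = col)
})
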