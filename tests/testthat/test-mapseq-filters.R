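test_that("spike-in normalization scales by the reference spike-in", {
    ## equal spike-ins: identity
    t1 <- makeTable(matrix(c(500, 0, 50, 0, 0, 20, 0, 0), 1), normalized = FALSE)
    n1 <- normalizeBySpikein(t1)
    expect_equal(bcCounts(n1), bcCounts(t1))
    expect_true(isNormalized(n1))
    expect_error(normalizeBySpikein(n1), "already")

    ## sample at half the reference: counts doubled
    sp <- c(1000, 500, 1000, 1000, 1000, 1000, 1000, 1000)
    t2 <- makeTable(matrix(c(100, 40, 50, 0, 0, 20, 0, 0), 1),
                    spikein = sp, normalized = FALSE)
    n2 <- normalizeBySpikein(t2)
    expect_equal(unname(bcCounts(n2)[1, "vMEC"]), 80)
    expect_equal(unname(bcCounts(n2)[1, "dMEC"]), 100)

    ## single barcode, count 10 against spike-ins (100, 50): (10, 20)
    t3 <- makeTable(matrix(c(10, 10, 10, 0, 0, 10, 0, 0), 1),
                    spikein = c(100, 50, 100, 100, 100, 100, 100, 100),
                    normalized = FALSE)
    n3 <- normalizeBySpikein(t3)
    expect_equal(unname(bcCounts(n3)[1, c("dMEC", "vMEC")]), c(10, 20))

    ## within-sample ratios unchanged
    set.seed(21)
    t4 <- makeTable(matrix(stats::rpois(160, 40), 20),
                    spikein = sample(500:1500, 8), normalized = FALSE)
    n4 <- normalizeBySpikein(t4)
    for (j in 1:8) {
        a <- bcCounts(t4)[, j]; b <- bcCounts(n4)[, j]
        nz <- a > 0
        if (sum(nz) > 1)
            expect_equal(stats::sd(b[nz] / a[nz]), 0)
    }
})

test_that("orphan barcodes (no injection-site counts) are removed", {
    tab <- makeTable(rbind(
        c(0, 0, 50, 0, 0, 0, 0, 0),      # orphan
        c(0, 3, 10, 0, 0, 5, 0, 0),      # kept: vMEC > 0
        c(5, 0, 10, 0, 0, 5, 0, 0)))     # kept
    r <- dropOrphans(tab)
    expect_equal(r$removed, 1L)
    expect_equal(nrow(r$table), 2L)
    ## all-zero injection columns: empty table
    allOrphan <- makeTable(rbind(c(0, 0, 5, 0, 0, 1, 0, 0),
                                 c(0, 0, 9, 1, 0, 0, 0, 0)))
    expect_equal(nrow(dropOrphans(allOrphan)$table), 0L)
})

test_that("control floor uses the nearest-rank percentile and zeros counts", {
    ## control column {0 x 9, 2}: nearest-rank 90th percentile = 0
    cts <- cbind(dMEC = rep(1000, 10), vMEC = 0, isocortex = 50, CNU = 0,
                 OlfCtxsp = 0, dHip = 20, vHip = 0,
                 control = c(rep(0, 9), 2))
    r <- applyControlFloor(makeTable(cts))
    expect_equal(r$threshold, 0)
    expect_equal(bcCounts(r$table)[, "isocortex"], rep(50, 10),
                 ignore_attr = TRUE)

    ## controls mostly 1: percentile 1, all counts of 1 become 0
    cts2 <- cbind(dMEC = rep(1000, 10), vMEC = 1, isocortex = c(1, rep(50, 9)),
                  CNU = 0, OlfCtxsp = 0, dHip = 20, vHip = 0,
                  control = c(rep(1, 9), 3))
    r2 <- applyControlFloor(makeTable(cts2))
    expect_equal(r2$threshold, 1)
    expect_equal(unname(bcCounts(r2$table)[, "vMEC"]), rep(0, 10))
    expect_equal(unname(bcCounts(r2$table)[1, "isocortex"]), 0)
    expect_equal(unname(bcCounts(r2$table)[2, "isocortex"]), 50)

    ## brute-force percentile on ten explicit values
    vals <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2)
    expect_equal(sort(vals)[ceiling(0.9 * 10)], 0)
})

test_that("each drop stage matches its brute-force row predicate", {
    for (seed in 1:25) {
        tab <- randomTable(sample(1:50, 1), seed = seed)
        cts <- bcCounts(tab)
        expect_equal(which(rownames(tab) %in%
                               rownames(dropOrphans(tab)$table)),
                     bruteSurvivors(cts, "orphans"))
        expect_equal(which(rownames(tab) %in%
                               rownames(dropTargetExceedsInjection(tab)$table)),
                     bruteSurvivors(cts, "target_exceeds"))
        expect_equal(which(rownames(tab) %in%
                               rownames(dropNonTelencephalic(tab)$table)),
                     bruteSurvivors(cts, "non_telencephalic"))
        expect_equal(which(rownames(tab) %in%
                               rownames(dropLowInjection(tab, 400)$table)),
                     bruteSurvivors(cts, "low_injection", 400))
        expect_equal(which(rownames(tab) %in%
                               rownames(dropLowTargets(tab, 10)$table)),
                     bruteSurvivors(cts, "low_targets", 10))
    }
})

test_that("filter boundaries are strict where specified", {
    ## injection 399 removed, 400 kept (rule is 'less than 400')
    tab <- makeTable(rbind(c(399, 0, 50, 0, 0, 5, 0, 0),
                           c(400, 0, 50, 0, 0, 5, 0, 0)))
    r <- dropLowInjection(tab)
    expect_equal(rownames(r$table), rownames(tab)[2])
    ## max target 9 removed, 10 kept
    tab <- makeTable(rbind(c(1000, 0, 9, 2, 1, 3, 2, 0),
                           c(1000, 0, 10, 0, 0, 0, 0, 0)))
    r <- dropLowTargets(tab)
    expect_equal(rownames(r$table), rownames(tab)[2])
    ## target equal to injection kept (strict inequality for removal)
    tab <- makeTable(rbind(c(60, 40, 150, 0, 0, 0, 0, 0),    # 150 > 100: out
                           c(60, 40, 100, 0, 0, 0, 0, 0)))   # 100 = 100: kept
    r <- dropTargetExceedsInjection(tab)
    expect_equal(rownames(r$table), rownames(tab)[2])
})

test_that("drop stages are idempotent and only ever remove rows", {
    stages <- list(dropOrphans, dropTargetExceedsInjection,
                   dropNonTelencephalic,
                   function(x) dropLowInjection(x, 400),
                   function(x) dropLowTargets(x, 10))
    for (seed in 26:30) {
        tab <- randomTable(40, seed = seed)
        for (f in stages) {
            once <- f(tab)
            expect_equal(f(once$table)$removed, 0L)     # idempotent
            expect_true(all(rownames(once$table) %in% rownames(tab)))
            expect_equal(bcCounts(once$table),
                         bcCounts(tab)[rownames(once$table), , drop = FALSE])
        }
    }
})

test_that("pipeline report removals account exactly for the row change", {
    sim <- simulateMapseq(mapseqSimParams(nNeurons = 400, seed = 5))
    res <- runFilterPipeline(sim$table)
    st <- filterStages(res$report)
    expect_equal(sum(st$n_removed), nrow(sim$table) - nrow(res$table))
    expect_true(all(st$n_removed >= 0))
    expect_true(validObject(res$report))
    ## narrative order of stages
    expect_equal(st$stage,
                 c("normalize_by_spikein", "drop_orphans", "control_floor",
                   "drop_target_exceeds_injection", "drop_non_telencephalic",
                   "drop_low_injection", "drop_low_targets"))
})

test_that("an empty table passes through the pipeline untouched", {
    empty <- makeTable(matrix(numeric(0), nrow = 0, ncol = 8),
                       normalized = FALSE)
    res <- runFilterPipeline(empty)
    expect_equal(nrow(res$table), 0L)
    expect_true(all(filterStages(res$report)$n_removed == 0))
})

test_that("constructed collateral-only data loses nothing beyond orphans", {
    sim <- simulateMapseq(mapseqSimParams(nNeurons = 300, collateralProb = 1,
                                          contaminationRate = 0,
                                          orphanRate = 0, seed = 8))
    res <- runFilterPipeline(sim$table)
    st <- filterStages(res$report)
    expect_equal(st$n_removed[st$stage == "drop_non_telencephalic"], 0L)
    expect_equal(st$n_removed[st$stage == "drop_orphans"], 0L)
})
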