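# Independent brute-force oracles the implementation is checked against.

# Exact signed-rank p by exhaustive enumeration of all 2^m sign vectors.
bruteWilcoxP <- function(d, alternative = "two.sided") {
    d <- d[d != 0]
    m <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
    Wnull <- apply(signs, 1L, function(s) sum(r[s]))
    pG <- mean(Wnull >= W - 1e-9)
    pL <- mean(Wnull <= W + 1e-9)
    switch(alternative,
           greater = pG, less = pL,
           two.sided = min(1, 2 * min(pG, pL)))
}

# Per-row survival predicates for each filter stage, evaluated naively.
ORDERED_ROLES <- c("injection", "injection", "telencephalic", "telencephalic",
                   "telencephalic", "hippocampal", "hippocampal", "control")

bruteSurvivors <- function(counts, stage, threshold = NULL) {
    inj <- rowSums(counts[, 1:2, drop = FALSE])
    tel <- counts[, 3:5, drop = FALSE]
    targets <- counts[, 3:7, drop = FALSE]
    keep <- switch(stage,
        orphans = inj > 0,
        target_exceeds = apply(targets, 1L, max) <= inj,
        non_telencephalic = rowSums(tel) > 0,
        low_injection = inj >= threshold,
        low_targets = apply(targets, 1L, max) >= threshold)
    unname(which(keep))
}

# Quick BarcodeExperiment from a bare counts matrix in canonical column order.
makeTable <- function(counts, spikein = rep(1000, 8), normalized = TRUE) {
    counts <- matrix(counts, ncol = 8L,
                     dimnames = list(NULL,
                                     c("dMEC", "vMEC", "isocortex", "CNU",
                                       "OlfCtxsp", "dHip", "vHip", "control")))
    BarcodeExperiment(counts, role = ORDERED_ROLES, spikein = spikein,
                      position = c("dorsal", "ventral", NA, NA, NA,
                                   "dorsal", "ventral", NA),
                      normalized = normalized)
}

randomTable <- function(n, seed) {
    set.seed(seed)
    counts <- matrix(stats::rpois(n * 8L, 3) *
                         sample(c(0, 1, 10, 100, 500), n * 8L, replace = TRUE),
                     nrow = n)
    makeTable(counts)
}
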