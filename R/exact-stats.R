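#' Exact paired Wilcoxon signed-rank test
#'
#' Small-sample exact test for paired differences, as used for
#' per-animal comparisons of axon density between regions (n = 5 or 6
#' mice). Zero differences are dropped before ranking (the classical
#' procedure), absolute differences are ranked with midranks for ties,
#' and the p-value is computed from the exact null distribution of the
#' positive-rank sum W+ over all 2^m equally likely sign assignments —
#' so the test remains exact in the presence of ties, which the base
#' `wilcox.test` exact path does not allow.
#'
#' With n = 5 differences all of one sign the one-tailed p is
#' 1/32 = 0.03125; with n = 6, 1/64 = 0.015625.
#'
#' @param diffs numeric vector of per-unit differences
#' @param alternative `"two.sided"`, `"greater"` (positive shift) or
#'   `"less"`
#' @param exactMax above this many nonzero differences the normal
#'   approximation (with tie correction and continuity correction) is
#'   used instead of exhaustive enumeration
#' @return list with `statistic` (W+, the sum of ranks of positive
#'   differences), `p.value`, `n` (nonzero differences used), `exact`.
#' @examples
#' wilcoxonSignedRankExact(c(0.2, 0.1, 0.3, 0.15, 0.25),
#'                         alternative = "greater")$p.value  # 1/32
#' @export
wilcoxonSignedRankExact <- function(diffs,
                                    alternative = c("two.sided", "greater",
                                                    "less"),
                                    exactMax = 25L) {
    alternative <- match.arg(alternative)
    stopifnot(is.numeric(diffs), length(diffs) >= 2L)
    if (anyNA(diffs))
        stop("missing values in diffs")
    d <- diffs[diffs != 0]
    if (!length(d)) {
        warning("all differences are zero; p = 1")
        return(list(statistic = NA_real_, p.value = 1, n = 0L, exact = TRUE))
    }
    r <- rank(abs(d))                       # midranks for ties
    W <- sum(r[d > 0])
    if (length(d) <= exactMax) {
        dist <- .signedRankNull(r)
        ## doubled ranks are integers; W on the doubled scale
        w2 <- round(2 * W)
        pGreater <- sum(dist$prob[dist$sum2 >= w2 - 1e-9])
        pLess <- sum(dist$prob[dist$sum2 <= w2 + 1e-9])
        exact <- TRUE
    } else {
        m <- length(d)
        mu <- m * (m + 1) / 4
        tieTab <- table(r)
        sigma <- sqrt(m * (m + 1) * (2 * m + 1) / 24 -
                      sum(tieTab^3 - tieTab) / 48)
        pGreater <- stats::pnorm(W - 0.5, mu, sigma, lower.tail = FALSE)
        pLess <- stats::pnorm(W + 0.5, mu, sigma)
        exact <- FALSE
    }
    p <- switch(alternative,
                greater = pGreater,
                less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
    list(statistic = W, p.value = min(1, p), n = length(d), exact = exact)
}

## Exact null distribution of the positive-rank sum, on doubled ranks so
## midranks (k + 0.5) become integers. Convolution over sign assignments:
## each rank contributes 0 or its value, each with probability 1/2.
.signedRankNull <- function(ranks) {
    r2 <- round(2 * ranks)
    S <- sum(r2)
    prob <- numeric(S + 1L)
    prob[1L] <- 1
    for (v in r2) {
        shifted <- c(numeric(v), prob[seq_len(S + 1L - v)])
        prob <- (prob + shifted) / 2
    }
    list(sum2 = 0:S, prob = prob)
}

#' Upper-tail probability of the chi-squared distribution
#'
#' Survival function used to convert a reported chi-squared statistic to
#' its p-value; for df = 1 it equals erfc(sqrt(x/2)).
#'
#' @param x non-negative chi-squared statistic
#' @param df degrees of freedom (>= 1)
#' @return P(X >= x) for X ~ chi-squared(df).
#' @examples
#' chiSqTail(1.9071, 1)  # ~0.1673
#' @export
chiSqTail <- function(x, df = 1) {
    if (any(!is.finite(x)) || any(x < 0))
        stop("x must be non-negative")
    if (any(df < 1))
        stop("df must be >= 1")
    stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Used for comparing response proportions between cell groups (e.g.
#' responsive vs non-responsive neurons in proximal vs distal CA1).
#' Yates continuity correction is off by default.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   row and column margins
#' @param correct apply the Yates continuity correction
#' @return list with `statistic` (X-squared), `df` (1), `p.value`,
#'   `method`.
#' @export
chiSq2x2 <- function(tab, correct = FALSE) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 2L)))
        stop("tab must be 2x2")
    if (any(tab < 0) || any(tab != round(tab)))
        stop("tab must hold non-negative integer counts")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("all row and column margins must be positive")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ht$statistic), df = 1L,
         p.value = unname(ht$p.value), method = ht$method)
}

#' Student's t-test with explicit degenerate-variance handling
#'
#' Paired or two-sample (pooled-variance) Student's t-test. Data with
#' zero variance — where `stats::t.test` errors — are handled by
#' convention: equal means give p = 1, a constant nonzero difference
#' gives p = 0 (in the favoured direction), and the result is flagged
#' `degenerate`.
#'
#' @param a numeric vector (first group, or the per-unit first
#'   measurement when `paired`)
#' @param b numeric vector (second group); omit for a one-sample test
#'   of `a` against zero
#' @param paired paired test on `a - b`
#' @param alternative `"two.sided"`, `"greater"` or `"less"`
#' @param varEqual pooled variance for the two-sample test (classical
#'   Student)
#' @return list with `statistic`, `df`, `p.value`, `degenerate`,
#'   `method`.
#' @export
studentT <- function(a, b = NULL, paired = FALSE,
                     alternative = c("two.sided", "greater", "less"),
                     varEqual = TRUE) {
    alternative <- match.arg(alternative)
    degenerateP <- function(delta) {
        if (delta == 0)
            return(1)
        switch(alternative,
               two.sided = 0,
               greater = if (delta > 0) 0 else 1,
               less = if (delta < 0) 0 else 1)
    }
    if (paired || is.null(b)) {
        d <- if (is.null(b)) a else a - b
        stopifnot(length(d) >= 2L)
        if (stats::sd(d) == 0) {
            delta <- mean(d)
            return(list(statistic = if (delta == 0) 0 else Inf * sign(delta),
                        df = length(d) - 1L, p.value = degenerateP(delta),
                        degenerate = TRUE, method = "paired t-test (degenerate)"))
        }
        ht <- stats::t.test(d, alternative = alternative)
    } else {
        stopifnot(length(a) >= 2L, length(b) >= 2L)
        if (stats::sd(a) == 0 && stats::sd(b) == 0) {
            delta <- mean(a) - mean(b)
            return(list(statistic = if (delta == 0) 0 else Inf * sign(delta),
                        df = length(a) + length(b) - 2L,
                        p.value = degenerateP(delta), degenerate = TRUE,
                        method = "two-sample t-test (degenerate)"))
        }
        ht <- stats::t.test(a, b, alternative = alternative,
                            var.equal = varEqual)
    }
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, degenerate = FALSE, method = ht$method)
}
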