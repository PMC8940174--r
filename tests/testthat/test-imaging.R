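roiOf <- function(img) c(rowStart = 1, rowEnd = nrow(img),
                         colStart = 1, colEnd = ncol(img))

test_that("radial profile bins, normalizes, and flags empty ROIs", {
    ## uniform image: every normalized bin is 1
    u <- matrix(1, 100, 40)
    p <- radialProfile(u, roiOf(u))
    expect_length(p@normalized, 20L)
    expect_equal(p@normalized, rep(1, 20))
    ## signal confined to the first quarter of the radial extent
    img <- matrix(0.1, 100, 40)
    img[1:25, ] <- 1
    p <- radialProfile(img, roiOf(img))
    expect_equal(p@normalized[1:5], rep(1, 5))
    expect_equal(p@normalized[7:20], rep(0.1, 14))
    ## flipped axis reverses the profile
    pf <- radialProfile(img, roiOf(img), flip = TRUE)
    expect_equal(pf@normalized, rev(p@normalized))
    ## positive scaling leaves the normalized profile unchanged
    p3 <- radialProfile(3.7 * img, roiOf(img))
    expect_equal(p3@normalized, p@normalized)
    ## all-zero ROI: unnormalized with flag
    z <- matrix(0, 60, 10)
    pz <- radialProfile(z, roiOf(z))
    expect_false(pz@normalizedValid)
    expect_true(all(is.na(pz@normalized)))
    expect_error(radialProfile(u, c(rowStart = 1, rowEnd = 200,
                                    colStart = 1, colEnd = 10)), "bounds")
})

test_that("fluorescence density is the above-threshold pixel fraction", {
    img <- matrix(c(rep(0, 50), rep(1, 50)), 10, 10)
    mask <- matrix(TRUE, 10, 10)
    expect_equal(fluorescenceDensity(img, mask, 0.5), 0.5)
    expect_equal(fluorescenceDensity(img, mask, 2), 0)      # above max
    ## monotone non-increasing in the threshold
    set.seed(2)
    img <- matrix(runif(400), 20, 20)
    d <- vapply(seq(0, 1, by = 0.1),
                function(th) fluorescenceDensity(img, matrix(TRUE, 20, 20), th),
                numeric(1))
    expect_true(all(diff(d) <= 0))
    expect_error(fluorescenceDensity(img, matrix(FALSE, 20, 20), 0.5), "empty")
})

test_that("pair normalization scales to unit sum and is scale invariant", {
    expect_equal(normalizePair(0.3, 0.1), c(0.75, 0.25))
    expect_equal(normalizePair(0.2, 0.2), c(0.5, 0.5))
    set.seed(3)
    for (rep in 1:5) {
        d <- runif(2)
        expect_equal(sum(normalizePair(d[1], d[2])), 1)
        expect_equal(normalizePair(5 * d[1], 5 * d[2]),
                     normalizePair(d[1], d[2]))
    }
    expect_error(normalizePair(0, 0), "both")
    expect_error(normalizePair(-0.1, 0.2), "non-negative")
})

test_that("paired regional comparison reproduces the exact Wilcoxon p-values", {
    ## 5 mice, distal > proximal in all: one-tailed p = 0.03125
    r5 <- compareRegions(c(0.7, 0.8, 0.6, 0.9, 0.75),
                         c(0.3, 0.2, 0.4, 0.1, 0.25), "greater")
    expect_equal(r5$p.value, 0.03125)
    ## 6 mice, deep > superficial in all: p = 0.015625
    r6 <- compareRegions(seq(0.6, 0.85, by = 0.05),
                         seq(0.4, 0.15, by = -0.05), "greater")
    expect_equal(r6$p.value, 0.015625)
    expect_warning(r0 <- compareRegions(c(1, 1, 1), c(1, 1, 1), "greater"))
    expect_equal(r0$p.value, 1)
    expect_error(compareRegions(1, 2), "two animals")
})

test_that("synthetic laminar densities are recovered within 20%", {
    im <- simulateLaminarImage(c(deep = 0.3, sup = 0.1), size = c(200, 400),
                               noiseSd = 0.02, seed = 1)
    mkMask <- function(l) {
        m <- matrix(FALSE, 200, 400)
        m[im$layers$rowStart[l]:im$layers$rowEnd[l], ] <- TRUE
        m
    }
    d <- c(fluorescenceDensity(im$image, mkMask(1), 0.5),
           fluorescenceDensity(im$image, mkMask(2), 0.5))
    ## against recorded ground truth (near exact: clean threshold separation)
    expect_equal(d, im$layers$realizedDensity, tolerance = 0.02)
    ## nominal 3:1 layer contrast recovered within 20%
    expect_lt(abs(d[1] / d[2] - 3) / 3, 0.2)
    ## equal densities give a flat 20-bin profile within the generator's
    ## own binomial bin-to-bin variation (~7% per bin here)
    flat <- simulateLaminarImage(rep(0.2, 4), size = c(400, 400), seed = 2)
    p <- radialProfile(flat$image, flat$roi)
    expect_gt(min(p@normalized), 0.65)
    expect_lt(stats::sd(p@binMeans) / mean(p@binMeans), 0.15)
    ## determinism and validation
    again <- simulateLaminarImage(c(deep = 0.3, sup = 0.1),
                                  size = c(200, 400), noiseSd = 0.02, seed = 1)
    expect_identical(im$image, again$image)
    expect_error(simulateLaminarImage(c(0.3, 1.5)), "\\[0, 1\\]")
    expect_error(simulateLaminarImage(0.2, size = c(0, 10)), "positive")
})

test_that("density pair objects validate and print consistently", {
    im <- simulateLaminarImage(c(a = 0.25, b = 0.05), size = c(100, 200),
                               seed = 5)
    mk <- function(l) {
        m <- matrix(FALSE, 100, 200)
        m[im$layers$rowStart[l]:im$layers$rowEnd[l], ] <- TRUE
        m
    }
    dp <- densityPair(im$image, mk(1), mk(2), 0.5,
                      labels = c("proximal", "distal"))
    expect_s4_class(dp, "DensityPair")
    expect_equal(sum(dp@normalized), 1)
    expect_true(validObject(dp))
})
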