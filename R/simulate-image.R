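#' Generate a synthetic laminar fluorescence image
#'
#' Emulates a single-channel section image of axonal labelling across
#' layers: the image is divided into horizontal layer bands (rows =
#' radial axis), and each layer receives short high-intensity horizontal
#' segments ("axons") at the requested areal density over a noisy
#' background. The realized per-layer density (fraction of pixels
#' actually painted, accounting for segment overlap and clipping) is
#' recorded as ground truth.
#'
#' @param layerDensities numeric vector of target areal densities in
#'   [0, 1], one per layer, in radial order; names become layer labels
#' @param size image size in pixels, c(rows, cols)
#' @param noiseSd Gaussian background noise SD (intensity units; the
#'   image is on a [0, 1]-ish intensity scale)
#' @param seed optional integer seed
#' @param segLen axon segment length, pixels
#' @param axonIntensity intensity of axon pixels
#' @param background mean background intensity
#' @return list with `image` (numeric matrix), `layers` (data.frame:
#'   layer, rowStart, rowEnd, targetDensity, realizedDensity) and `roi`
#'   (named vector rowStart, rowEnd, colStart, colEnd spanning the whole
#'   image).
#' @examples
#' im <- simulateLaminarImage(c(SP_deep = 0.3, SP_sup = 0.1), seed = 1)
#' @export
simulateLaminarImage <- function(layerDensities, size = c(400L, 400L),
                                 noiseSd = 0.02, seed = NULL, segLen = 8L,
                                 axonIntensity = 0.9, background = 0.1) {
    if (any(!is.finite(layerDensities)) || any(layerDensities < 0) ||
        any(layerDensities > 1))
        stop("layer densities must lie in [0, 1]")
    if (length(size) != 2L || any(size < 1))
        stop("image size must be two positive pixel counts")
    if (!is.null(seed))
        set.seed(seed)
    H <- as.integer(size[1L]); W <- as.integer(size[2L])
    nL <- length(layerDensities)
    edges <- round(seq(0L, H, length.out = nL + 1L))
    painted <- matrix(FALSE, H, W)
    layers <- data.frame(
        layer = if (!is.null(names(layerDensities))) names(layerDensities)
                else sprintf("layer%d", seq_len(nL)),
        rowStart = edges[-(nL + 1L)] + 1L, rowEnd = edges[-1L],
        targetDensity = as.numeric(layerDensities),
        realizedDensity = NA_real_)
    for (l in seq_len(nL)) {
        rows <- layers$rowStart[l]:layers$rowEnd[l]
        nPix <- length(rows) * W
        nSeg <- round(layerDensities[l] * nPix / segLen)
        if (nSeg > 0) {
            segRow <- sample(rows, nSeg, replace = TRUE)
            segCol <- sample.int(W, nSeg, replace = TRUE)
            for (s in seq_len(nSeg))
                painted[segRow[s], segCol[s]:min(W, segCol[s] + segLen - 1L)] <- TRUE
        }
        layers$realizedDensity[l] <-
            sum(painted[rows, , drop = FALSE]) / nPix
    }
    img <- background + stats::rnorm(H * W, 0, noiseSd)
    dim(img) <- c(H, W)
    img[painted] <- axonIntensity + stats::rnorm(sum(painted), 0, noiseSd)
    list(image = img, layers = layers,
         roi = c(rowStart = 1L, rowEnd = H, colStart = 1L, colEnd = W))
}
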