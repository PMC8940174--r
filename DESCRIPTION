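Package: collateseq
Title: Barcode-Based Projection Mapping of Entorhinal-Hippocampal Collaterals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying axon collateralization from MAPseq barcode
    sequencing data, built around the analysis of telencephalon-projecting
    neurons in layer 5a of the medial entorhinal cortex and their collaterals
    to hippocampal CA1. Provides the barcode count container and the spike-in
    normalization and count-filtering pipeline, co-projection and dorso-ventral
    topography statistics, the barcode-collision (unique labelling) closed form
    with a simulation oracle, current-clamp intrinsic-property extraction and
    hierarchical cell-type classification, optogenetic postsynaptic-potential
    response quantification (amplitude, onset latency, latency jitter,
    polarity), laminar fluorescence profiling and thresholded axon-density
    measurement, exact small-sample statistics (exact paired Wilcoxon
    signed-rank, 2x2 chi-squared, t-tests), and ground-truth-labelled synthetic
    data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
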