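---
title: "Methods: barcode-based collateralization analysis"
author: "collateseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-based collateralization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collateseq)
```

# Overview

`collateseq` analyses barcode-sequencing projection-mapping experiments in
which neurons of deep medial entorhinal cortex (MEC) are labelled with a
high-diversity RNA barcode library and barcode counts are read out in
dissected target areas: two injection-site samples (dorsal and ventral MEC),
three telencephalic divisions (isocortex, cerebral nuclei/striatum,
olfactory areas + cortical subplate), dorsal and ventral hippocampus, and at
least one negative-control area (brainstem/spinal cord, which receives no
axons from these cells). The scientific question is single-cell
collateralization: does a neuron that projects to the telencephalon also
send an axon branch to hippocampal CA1? The package also implements the
companion analyses used to validate such a projection — intrinsic
electrophysiology and cell-type classification of the postsynaptic targets,
optogenetically evoked PSP quantification, laminar fluorescence
quantification — and the exact small-sample statistics these experiments
need.

This vignette records the models, the parameters that matter, the numerical
conventions, and the design decisions taken where the procedure was
genuinely open.

# The barcode count model and the filtering pipeline

A `BarcodeExperiment` is a `SummarizedExperiment` of barcode x sample
counts. Filtering proceeds in a fixed narrative order
(`runFilterPipeline`), each stage audited:

1. **Spike-in normalization.** Each sample's counts are scaled by
   (reference spike-in / sample spike-in). The reference is the *maximum*
   spike-in across samples, so all scale factors are at least 1 and
   positive counts can never be scaled into the zero floor. Within-sample
   ratios are untouched.
2. **Orphan removal.** Barcodes with no injection-site counts have no
   identifiable soma and are presumed artifacts.
3. **Negative-control floor.** The 90th percentile of *all* control-sample
   counts (zeros included) is computed with the nearest-rank convention
   (`sorted[ceiling(p/100 * n)]` — deterministic, and well defined for
   small samples), and every count at or below it, in every sample, is set
   to zero. In the original data this floor was 1, i.e. "counts of 1 become
   0"; the package implements the general percentile rule of which that is
   the observed special case.
4. **Target-exceeds-injection removal.** A target count cannot legitimately
   exceed the soma-side count; rows where the maximum target count strictly
   exceeds the injection count are removed (dissection spillover).
5. **Non-telencephalic removal.** Rows with no counts in any telencephalic
   division carry no information for the collateralization question; this
   simultaneously removes hippocampus-only rows.
6. **Minimum injection count (default 400)** and
7. **minimum target count (default 10)**, guarding against incomplete
   barcode transport and PCR/polymerase false positives respectively.

Decisions where the procedure was open:

- **"Injection site" count = dMEC + vMEC.** A soma sits in one dissection
  block, but blocks can straddle the dorso-ventral cut; the sum is robust
  to straddling and is used for the orphan, exceeds-injection and
  minimum-injection rules.
- **Thresholds 400 and 10 apply to spike-in-normalized counts**, because
  both rules follow normalization in the pipeline order. With the maximum
  spike-in as reference, normalized counts are never smaller than raw ones.
- **"Detected" means count > 0 after all filters**, consistent with the
  control floor zeroing sub-threshold counts.

# Projection statistics

- **Co-projection proportion** per division:
  `100 * n(division-positive and hippocampus-positive) / n(division-positive)`.
  A barcode contributes to every division it is detected in. An empty
  division yields NA with a warning rather than 0.
- **Origin classification** is a strict comparison (dMEC > vMEC = dorsal,
  reverse = ventral); exact ties are a third category, excluded from
  origin-stratified displays and counted separately, because the defining
  rule covers only the two strict cases.
- **Hippocampal projection strength** normalizes each hippocampus-positive
  row to `pctDHip + pctVHip = 100`. The topography matrix groups rows by
  origin (dorsal first) and sorts within group by maximal projection site
  and then strength descending — a stable, deterministic ordering for
  heatmaps.
- **Contamination** is measured after normalization but before the control
  floor, as the percentage of barcodes with any control-area count.

Per-brain versus pooled summaries: `coprojectionSummary` operates on one
table (one brain); multi-brain means with SEM are computed by applying it
per brain and averaging, which is how small-n animal studies report such
proportions.

# Barcode collisions

With `k` neurons drawing barcodes uniformly from a library of diversity
`N`, the expected fraction of uniquely labelled neurons is
`F = (1 - 1/N)^(k-1)`, evaluated in log space
(`exp((k-1) * log1p(-1/N))`) so that `N` of millions does not lose
precision. `simulateUniqueFraction` is an independent Monte-Carlo oracle:
it draws the labels and counts the neurons whose label is unshared. `k` is
always an explicit argument — an anatomical neuron count is an upper bound
on infected neurons, so baking it in would overstate certainty. No
correction is attempted for one neuron carrying several barcodes; that
overrepresentation does not change projection patterns.

# The synthetic MAPseq generator

`simulateMapseq` emulates the experiment with recorded ground truth. Per
neuron: a dorsal or ventral origin (1:1), a set of telencephalic divisions
(independent Bernoulli draws with probabilities 0.5 / 0.5 / 0.4,
conditioned on at least one), a hippocampal collateral with probability
`collateralProb`, and a barcode drawn with replacement from `librarySize`
barcodes, so collisions occur at the analytic birthday rate; neurons
sharing a barcode are merged in the observed table, as they would be in
real data.

Counts are overdispersed: each projected-to area receives `1 + NB(mu,
size)` counts (negative binomial, dispersion `size = 2` by default —
sequencing counts are overdispersed and no noise model is prescribed by the
experiment itself). The `1 +` makes "projected implies detectable" true by
construction, which the recovery guarantees rely on. Topography and origin
are imposed *strictly*: the favoured side (hippocampal side matching the
origin with probability `dvGradient`, injection side matching the origin
always) receives `other + 1 + NB(...)` counts, so a perfect gradient
(`dvGradient = 1`) forces every dorsal-origin barcode to have
`pctDHip > 50` exactly, with no noise exceptions. Sample-specific capture
efficiency is emulated by scaling raw counts down to each sample's
spike-in total (with a ceiling, preserving positivity); normalization in
the pipeline inverts this. Contamination adds sporadic raw counts of
exactly 1 to non-projected target/control areas — mirroring the
observation that the control floor of 1 removed them — at a default rate
of 0.01, matching the ~1% of barcodes seen in control areas. Orphans
(default 2%) have their injection counts zeroed.

Defaults were chosen once to describe the emulated study: 2e6 library
diversity, collateralization 0.99 (the observed co-projection proportions
are 98–99%), mean soma-side count 5000 and mean target count 100 (well
clear of the 400/10 thresholds, as real surviving barcodes are), spike-in
totals varying by less than a factor of two across samples.

What the generator does *not* model: Sindbis virus biology, PCR chemistry,
dissection geometry, or any correlation structure between divisions beyond
independence. Passing recovery tests therefore shows the *pipeline* is
correct and calibrated, not that real tissue obeys these distributions.

A note on estimator bias: the minimum-target filter removes weak barcodes,
and a collateral barcode has two extra areas in which to clear the
threshold, so the post-pipeline co-projection fraction is very slightly
biased upward (order 0.002 at `collateralProb = 0.5` with default counts).
This is a property of the filtering itself, well inside the Monte-Carlo
tolerance the recovery checks use.

# The membrane model behind `simulateSweeps`

The generator produces the three protocols the analysis expects — a step
family (-40 to +40 pA in 20-pA increments, 1 s), a 50 pA/s ramp to 400 pA,
and a 1-s 200-pA step — from the simplest model that yields every required
feature:

- **Subthreshold**: closed-form RC responses
  (`dV = I * R * (1 - exp(-t/tau))`). Hyperpolarizing steps add an
  Ih-like sag component (a rise-and-relax kernel, relaxation time 150 ms)
  scaled so the steady-state/peak deflection ratio approximates the
  class's target sag.
- **Ramp spikes**: leaky integrate-and-fire threshold crossings, solved
  segment-wise in closed form between spikes, with a stereotyped AP
  waveform pasted at each crossing and a per-spike threshold increment for
  adaptation. The waveform is a linear rise (60% of the nominal half-width)
  to `threshold + apAmp`, then a linear fall to `threshold - AHP` whose
  duration is chosen so the width at half spike amplitude equals the
  nominal half-width exactly, accounting for the flank continuing below
  threshold.
- **200-pA step**: a deterministic accommodating inter-spike-interval
  schedule (`ISI_k` relaxing exponentially from `ISI_1` to `ISI_inf`) on a
  rising backbone — transparent control over the first and last ISI, which
  are exactly the measured maximum and base frequencies.

Class parameter boxes (pyramidal: max frequency < 50 Hz, AHP < 10 mV,
half-width >= 0.7 ms, sag <= 0.9; fast-spiking: >= 100 Hz, >= 12 mV,
< 0.5 ms, > 0.9; non-fast-spiking: 50–100 Hz, >= 12 mV, 0.5–0.9 ms,
> 0.9) are satisfied with margins chosen a priori to survive 1 mV of
recording noise: e.g. the fast-spiking sag target is 0.98 against the 0.9
boundary because the trough of a noisy hyperpolarizing step is found as a
minimum and is therefore biased downward by roughly the smoothed noise
floor. First-spike latencies are class-specific (2 ms for fast-spiking,
15 ms for pyramidal cells), which also keeps the count-based mean firing
rate above the terminal instantaneous rate on accommodating trains.

## Feature-extraction conventions

- **AP threshold** is the voltage at the first crossing of dV/dt >= 20 V/s
  before the first peak — the standard convention. The derivative is a
  central difference over a centred 0.2-ms running mean; a candidate onset
  only counts as a spike if the trace rises at least 20 mV above the onset
  voltage within 5 ms, which rejects noise-driven derivative crossings.
- **Input resistance** uses the largest *subthreshold* depolarizing step
  (spiking sweeps would corrupt the steady state), steady state = mean
  over the last 20% of the step.
- **Sag** deflections are measured relative to the pre-step baseline; the
  literal ratio of absolute voltages would depend on the resting potential
  sign convention. The trough search smooths with a 5-ms window and
  excludes the edge half-windows, where a centred mean degenerates to
  nearly raw samples and a noise outlier can pose as the trough.
- **AHP** is threshold minus the minimum between the first peak and the
  next spike onset (or +100 ms).
- **QC**: recordings with RMP above -50 mV or bridge balance above 40 MOhm
  are excluded (strict inequalities, so exactly 40 MOhm passes).
- **Classification** evaluates the criteria in the stated descending order.
  The three frequency bands partition the axis, so the first criterion
  picks a unique candidate class; by default (`requireAll = TRUE`) the
  remaining three criteria must also hold, otherwise the cell is
  unclassified — matching the exclusion of cells that fit no class.
  `requireAll = FALSE` lets the frequency band alone decide, for the
  hierarchical reading in which earlier criteria take precedence.

# PSP analysis

Per trial, baseline is the mean over the 10 ms before the stimulus and the
response peak is sought within 50 ms after it — windows sized to
accommodate ~3-ms monosynaptic latencies, and configurable. The
responsiveness test is a two-tailed paired Student's t-test of per-trial
peaks against baselines ("type one" in the spreadsheet convention = paired,
matching the per-trial pairing).

The one methodological subtlety is peak selection. Searching each trial's
own window maximum makes the test wildly anticonservative: the maximum of
noise is positive in expectation. Even estimating a common peak time from
all trials leaves the *mean* peak biased, because the time is chosen to
maximize nearly the same average being tested. `pspAnalyze` therefore
cross-fits: trials are split into two halves, and each half is measured at
the peak time estimated from the *other* half's mean trace. Under the null
the measured values are exactly unbiased, and the test's type-I error is
nominal (checked by simulation in the test suite); under a real response
both halves estimate the same peak time and nothing is lost.

Onset latency per trial is the first crossing of baseline +/- 2 SD (of that
trial's baseline) toward the peak, sustained for 0.3 ms; onset rather than
peak latency is the default because jitter of the *onset* is the
monosynapticity argument. Latency jitter (SD across trials) is reported
only for responses exceeding 1 mV — below that, single-trial onset
detection is dominated by noise. Polarity is biphasic when the mean trace
has both a significant positive and negative excursion (each exceeding
4 baseline-SDs and a quarter of the larger excursion), otherwise the sign
of the amplitude.

The synthetic trials are alpha-function deflections (2-ms rise default —
no particular PSP shape is prescribed by the measurements) with
Gaussian-jittered onsets and additive noise; `"biphasic"` superimposes a
delayed inverted kernel.

# Laminar imaging

`radialProfile` divides a rectangular ROI into 20 equal bins along the
radial axis, takes per-bin mean intensities, and scales the maximum to 1;
an all-zero ROI is returned unnormalized with a flag instead of dividing
by zero. The bin direction default runs along increasing rows (stratum
oriens toward stratum moleculare in the intended orientation) with a
`flip` argument, since anatomical direction is a labelling convention.
`fluorescenceDensity` is the fraction of region pixels strictly above a
threshold; the manual threshold of the original workflow is replaced by an
explicit argument with a reproducible percentile-based default
(`autoThreshold`, 99th percentile). Pair normalization scales the two
regional densities to sum to 1 within a brain; per-brain averaging of
replicate sections is done before normalization (the default reading),
and the alternative is a one-line change at the call site. The proprietary
"median unsharp" background correction of the original imaging platform
is out of scope; images are assumed background-corrected, and the
synthetic generator produces signal-over-background images directly.

The synthetic laminar image paints short high-intensity segments at a
target areal density per layer and records the *realized* painted fraction
(overlap and edge clipping make it slightly lower than nominal — at a
nominal density of 0.3, overlap alone reduces coverage by about 10%,
which is why density-recovery checks compare against the recorded ground
truth and allow 20% on nominal ratios).

# Exact statistics

- **Exact paired Wilcoxon signed-rank** (`wilcoxonSignedRankExact`): zeros
  dropped (the classical procedure), midranks for ties, and the exact null
  distribution of the positive-rank sum over all `2^m` sign assignments,
  computed by convolution on doubled ranks (so midranks are integers).
  This remains exact under ties, which the base-R exact path refuses; the
  test suite checks it against brute-force enumeration for every n <= 10
  and against `wilcox.test` on tie-free data. Above 25 nonzero differences
  a tie-corrected normal approximation with continuity correction takes
  over (documented fallback). Two-sided p is `min(1, 2 * min(p_less,
  p_greater))`, the convention for symmetric discrete nulls.
- **Chi-squared**: `chiSq2x2` wraps the standard Pearson test; the Yates
  continuity correction is off by default, with a flag, because the
  original reports do not state whether it was applied and the printed
  statistics cannot disambiguate. `chiSqTail` is the upper-tail
  chi-squared probability, which for df = 1 equals `erfc(sqrt(x/2))` (the
  identity the tests verify to 1e-12).
- **Student's t** (`studentT`): paired or pooled-variance two-sample, with
  explicit conventions where the textbook statistic is undefined: zero
  variance with equal means gives p = 1, a constant nonzero difference
  gives p = 0, both flagged `degenerate`.

# Problem sizes and reproducibility

Every generator takes an explicit integer seed and is byte-reproducible.
The test suite exercises: collateralization recovery at 0.5 / 0.9 / 0.99
with 3000 neurons over 50 seeds each; filter-stage equivalence against
brute-force row predicates on 1000 random tables of up to 50 rows;
signed-rank enumeration for all n <= 10; classifier recovery on 300
synthetic cells at 1 mV noise (and noise-free determinism per class);
topography and laminar-density recovery on construction-guaranteed
gradients. These sizes give Monte-Carlo standard errors several times
smaller than the tolerances they are tested against.

# Limitations

- The pipeline starts from a barcode count matrix; FASTQ preprocessing,
  error correction and UMI collapsing are upstream of this package.
- The generators are calibration instruments, not tissue models: negative
  binomial independence across areas, alpha-function PSPs, and
  pasted-template APs are the simplest structures with the right measured
  features, and conclusions about real data rest on the analysis code, not
  on these forms.
- The co-projection estimator inherits a small upward bias from the
  minimum-target filter (see above); at realistic count depths it is an
  order of magnitude below the reported proportions' SEMs.
- No atlas registration, ROI drawing, or section-to-brain reconstruction:
  region masks and ROIs are inputs.
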