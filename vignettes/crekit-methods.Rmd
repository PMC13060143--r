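---
title: "Methods and design notes for crekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for crekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

crekit implements the bespoke computational steps of a multi-subset
T-cell regulatory-genomics workflow: quantifying episomal reporter
(STARR-seq) activity of open chromatin regions (OCRs) against an input DNA
library, projecting per-subset activity into a star-coordinate specificity
map, designing CRISPR tiling guide libraries, analyzing sorted-bin screen
counts, and quantifying chromatin-contact changes at loop anchors. This
vignette explains the models, the tunable parameters, what the synthetic
data does and does not emulate, and the numerical choices made where the
design was genuinely open.

## STARR-seq activity model

Reporter RNA fragments and input DNA fragments are counted into 50 bp
windows stepped every 25 bp (window starts are multiples of the step from
coordinate 0 of each chromosome — the anchor phase is a documented
convention, not biology), restricted to windows overlapping the union peak
set by at least 1 bp. Fragments are first filtered to 150–800 bp
(inclusive), because reporter output libraries carry a short (< 140 bp)
contaminant mode that the input lacks; per-sample retained counts are
reported. Composition bias between libraries is corrected with
trimmed-mean-of-M-values (TMM) factors computed on 2,500 bp background
bins (trim 30% on M, 5% on A, precision-weighted; reference column =
upper-quartile closest to the mean).

Per window and subset, counts are modeled as negative binomial with a log
link: one mean for the input DNA libraries, one for the subset's RNA
libraries, with log effective library size (library size × TMM factor) as
offset. Dispersions are method-of-moments estimates shrunk toward a lowess
abundance trend with 10 prior degrees of freedom; inference is a Wald *t*
test whose degrees of freedom add the prior df to the residual df. The
upstream method delegates this step to edgeR's quasi-likelihood machinery;
we deliberately implement a simpler test and treat **calibration and
recovery as the contract** — type-I error on null simulations sits at
≈ 0.045 at nominal 0.05, and planted 4-fold activations are recovered with
sensitivity ≥ 0.8 at FDR ≤ 0.10 (see `tests/testthat/test-acceptance.R`).
Bit-compatibility with edgeR is a non-goal.

Windows are merged into regions by chaining windows with gap ≤ 0 bp
(abutting half-open windows merge; a 1 bp gap does not); chains spanning
more than 3,000 bp are split at window boundaries into
`ceiling(span/3000)` sub-clusters of near-equal window count. Region-level
evidence uses a weighted-Holm order statistic: member p-values are
Holm-adjusted with the summit (highest-abundance) window given weight 4
(α-spending share; the magnitude is configurable because the upstream
method does not state it), and the combined p is the k-th smallest
adjusted value with `k = min(n, max(3, ceiling(0.4 n)))` — so a region is
only significant when at least k windows are individually significant.
The representative log2FC comes from the best-test window (smallest
adjusted p; ties broken toward larger |log2FC|). Benjamini–Hochberg across
regions then classifies each region as active (FDR ≤ 0.05, log2FC > 0),
repressive (log2FC < 0), or not significant. P-values are floored at
1e-300 before any log transform.

## Subset-specificity star projection

For regions with activity FDR < 0.01 in at least one subset, the
per-subset weight is `w_i = |log2FC_i| × (−log10 FDR_i)`, normalized to
shares `s_i = w_i / Σw`. Each of the n = 5 subsets gets a spoke at
`θ_i = 2πi/n`; the region's position is `x = Σ s_i cos θ_i`,
`y = Σ s_i sin θ_i`, radius `r = √(x² + y²)`. Pure single-subset activity
lands on the spoke with r = 1; uniform activity lands at the origin.
Regions with r > 0.85 are subset-preferred (up to 2,000 per dominant
subset, ranked by angular proximity to the spoke); r < 0.10 is shared (up
to 5,000, smallest radii first). The source legends disagree on the shared
threshold (0.10, 0.15, and 0.3 appear); we default to the Methods value
0.10 and expose both thresholds. All-zero-weight regions are excluded
rather than mapped to the origin so they cannot inflate the shared class.
Repressive activity participates via |log2FC| exactly as the formula
states. Motif-family enrichment between selected and background sets uses
two-sided Fisher exact tests with a Haldane–Anscombe 0.5 correction for
zero cells and BH adjustment across families.

## Guide library design

Candidates are all 20-mers immediately 5′ of an NGG PAM on either strand
(the 20 bp genomic footprint excludes the PAM, matching the accessibility
wording "each 20 bp gRNA target"). Filters: specificity score ≥ 0.2
(scores are consumed as input; the external scorer is out of scope) and no
GGGGG or TTTT substring. The accessibility score is, per subset, the mean
over replicates of the CPM-sum of ATAC fragments overlapping the
footprint, then the maximum over subset means. Selection is greedy in
descending accessibility, accepting a guide only if it overlaps every
previously accepted guide by ≤ 10 bp, capped at 10 (genome-scale) or 15
(targeted) per region. Score ties (the upstream method is silent) break
to the smaller start coordinate, then lexicographic protospacer — making
selection fully deterministic. NTCs are sized as 5% of the final library
(`n_ntc = round(n_targeting × f/(1−f))`), drawn GC-count-stratified from
the targeting distribution, and rejected if they match the genome on
either strand at Hamming distance ≤ 1 (a concrete reading of "did not
align"; stricter policies are configurable).

## Screen analysis

Reads are cropped to 20 nt (shorter reads dropped and counted), then
matched to the library exactly (default; synthetic reads are error-free)
or at Hamming ≤ 1 with ambiguous reads discarded; counting conserves
reads. Size factors are DESeq2-style median-of-ratios over guides with
all-positive counts. Per guide, an NB log-linear model of count on bin
(hi vs lo, positive = hi-enriched) plus a replicate covariate when ≥ 2
replicate pairs exist, with the same trend-shrunk dispersion and Wald *t*
machinery as the window test (prior df 20). Elements are significant with
≥ 1 guide at padj < 0.05 (the rule used in the source's extended
analysis; a k-of-n rule is configurable), and NTCs are summarized
separately as the empirical null.

## Contact-matrix tools

ICE balancing iterates `w ← w / sqrt(normalized marginal)` until the
coefficient of variation of non-masked marginals falls below 1e-6 (cap 500
iterations), masking bins with raw marginal below `min_count` (default 1)
or exactly zero; weights are rescaled so the mean non-masked balanced
marginal is 1 (a convention the upstream tooling leaves open). Expected
contact at distance d is the per-diagonal mean of the balanced matrix
within the captured locus (no genome-wide expected exists in a
region-capture context); O/E divides by it, so O/E diagonal means are 1 by
construction. APA is the mean O/E over a (2·flank+1)² window (flank 2 =
±1 kb at 500 bp bins), masked pixels excluded and windows > 50% masked
flagged. Differential maps use `log2((A+ε)/(B+ε))` with ε defaulting to
half the smallest positive value. Coarsening block-sums raw counts;
balancing is recomputed at the new resolution.

## What the synthetic data emulates — and what it does not

The generators plant machine-readable ground truth for every stage:

* **Activity truth**: regions are inactive, shared-active (multiplier 4 in
  all subsets), subset-specific (4 in exactly one), or repressive (0.25),
  with default class proportions 0.77/0.12/0.06/0.05 — matching the
  observed ~23% active fraction with a minority of repressive and
  subset-restricted elements.
* **Fragments**: input uniform over peaks with a 150–800 bp length mode
  (truncated gamma, mean ≈ 310 bp); RNA outputs share the geometry with
  rates × multiplier, plus a 30% short-fragment (< 140 bp) contaminant
  mode only in outputs, mirroring the observed input/output length
  asymmetry. Counts are Poisson with gamma replicate-level overdispersion
  (default 0.05, mild); 3 input and 3 RNA replicates per subset.
* **Screen counts**: negative binomial, expected hi/lo ratio
  `2^effect × bin-depth ratio`, depth 500 per guide, dispersion 0.05.
* **Contact maps**: power-law decay `(1+d)^(−1)`, planted loops multiply a
  ±`loop_spread`-bin neighborhood by the enrichment, Poisson sampling at
  depth 1e6, symmetric by construction.

Not emulated: motif grammar or TF-binding sequence structure (guide
specificity scores are Beta draws, not off-target computations), read
errors and quality scores, mapping artifacts, capture-probe bias, and
inter-replicate batch structure beyond a single overdispersion knob. A
green recovery test therefore establishes that the statistical machinery
recovers planted signals under the assumed noise model — not that the
pipeline is robust to artifacts the generators do not produce.

## Numerical and design choices

* **Loop footprint vs APA window.** The generator's default plants
  enrichment over a ±1-bin neighborhood while APA averages a ±2-bin
  window. A window mean over 25 pixels of which only 9 are enriched
  *cannot* equal the enrichment (it equals `(9E+16)/25`), so recovery
  analyses plant loops with `loop_spread` equal to the APA flank — the
  aggregation window then coincides with the planted footprint and the
  window mean is an unbiased estimator of the planted factor. A small
  (≈ 2–3%) downward bias remains because the loop inflates its own
  diagonal's expected value and its bins' ICE marginals.
* **Wald t with prior df** (rather than a likelihood-ratio χ²): with 3–6
  samples per contrast a χ² reference is anticonservative; adding the
  shrinkage prior df to the residual df gives type-I error ≈ 0.045–0.052
  at nominal 0.05 in both the window and guide tests.
* **Zero-count groups** in the two-group fit floor the group total at 1/8
  pseudo-fragment: estimates stay finite and the small Fisher information
  keeps such contrasts conservative.
* **Ties**: dominant subset → lowest subset index; best window → larger
  |log2FC|; guide score → smaller start, then protospacer.

## Known limitations

* The shared-class recovery invariant (≥ 90% of planted uniformly-active
  regions at r < 0.10) is **not met** and the corresponding acceptance
  expectation is deliberately left failing. The weight
  `|log2FC| × (−log10 FDR)` is roughly cubic in the per-subset effect
  estimate, so replicate-level overdispersion imposes a depth-independent
  variance floor (`var(log2FC) ≈ 2φ/n_reps ≈ 0.033` at φ = 0.05, n = 3) on
  the shares; the radius of truly uniform regions is then approximately
  Rayleigh with scale ≈ 0.06–0.08, and only ~60–85% fall below r = 0.10
  (≈ 88% below 0.15, ≈ 99% below 0.3). Deeper sequencing does not help;
  more replicates or a wider shared threshold would.
* The window test assumes a common dispersion structure across subsets and
  no replicate blocking (the upstream design is unstated); planted
  simulations are generated the same way, so this is untested against
  replicate-correlated noise.
* ICE is dense-matrix; intended for captured-locus scales (≤ a few
  thousand bins), not genome-wide maps.
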