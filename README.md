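# crekit

Functional characterization of cis-regulatory elements in CD4+ T-cell
subsets: an R package implementing the bespoke computational steps of a
multi-subset regulatory-genomics workflow, exercisable end-to-end on
synthetic data with planted ground truth.

**Who it is for.** Computational biologists analyzing episomal reporter
(ATAC-STARR-seq) activity of open chromatin regions (OCRs) across related
cell states, designing CRISPR tiling screens over those regions, reading
out sorted-bin screens, and quantifying loop-level contact changes in
region-capture Micro-C maps.

## What it computes

1. **STARR-seq activity** (`starr_pipeline`): fragments filtered to
   150–800 bp, counted into 50 bp / 25 bp-step sliding windows over the
   union peak set; per window and subset a negative-binomial log-linear
   test of RNA vs input DNA with TMM offsets; windows merged (gap ≤ 0 bp,
   max span 3,000 bp); region p-value = k-th smallest weighted-Holm
   adjusted member p (summit upweighted, k ≥ 3); BH FDR and
   active/repressive/not-significant classes.
2. **Subset specificity** (`specificity_profile`): per-subset weights
   `w_i = |log2FC_i|·(−log10 FDR_i)` normalized to shares `s_i`, projected
   to star coordinates `x = Σ s_i cos θ_i`, `y = Σ s_i sin θ_i` with
   spokes `θ_i = 2πi/5`; radius r classifies subset-preferred (r > 0.85)
   vs shared (r < 0.10); Fisher-exact motif-family enrichment between the
   classes.
3. **Guide design** (`design_guides`): NGG-adjacent 20-mer enumeration,
   specificity ≥ 0.2 and GGGGG/TTTT filters, ATAC-CPM accessibility
   scoring (max over subset means), greedy non-overlapping selection
   (≤ 10 bp pairwise overlap, 10 guides/region genome-scale), GC-matched
   non-targeting controls at 5% of the final library with a no-alignment
   guarantee (exact + 1-mismatch, both strands).
4. **Screen analysis** (`test_guides`, `aggregate_elements`): protospacer
   cropping, exact/one-mismatch counting, median-of-ratios size factors,
   NB hi-vs-lo test per guide, element calls (≥ 1 significant guide).
5. **Contact tools** (`ice_balance`, `observed_expected`, `apa`,
   `apa_ratio`, `differential_map`, `coarsen`): ICE balancing to equal
   marginals, per-diagonal O/E, aggregate peak analysis in ±2-bin windows
   at anchor pairs, control/perturbed APA ratios, log2 differential maps.
6. **Synthetic data** (`simulate_*`): genome, activity truth, STARR
   fragment libraries (with the short-fragment output contaminant), guide
   candidates, NB screen counts, distance-decay contact maps with planted
   loops — all seeded and emitting machine-readable truth.

See `vignettes/crekit-methods.Rmd` for models, parameter choices and
limitations.

## Worked example

```r
library(crekit)
res <- run_synthetic_study(seed = 1)
str(res$recovery)
#> List of 6
#>  $ activity_sensitivity: num 1
#>  $ activity_fdr        : num 0
#>  $ specific_recovered  : num 1
#>  $ shared_recovered    : num 0.595
#>  $ screen_sensitivity  : num 1
#>  $ apa_ratio           : num 1.42
```

Every planted active region is called active with no false positives
(`activity_sensitivity`, `activity_fdr`); every planted single-subset
region is classified subset-preferred with the correct dominant subset
(`specific_recovered`); 59.5% of uniformly-active regions land in the
shared class (the known limitation above); all planted-effect guide
elements are significant (`screen_sensitivity`); and the APA
control/perturbed ratio recovers the planted 1.5-fold loop depletion to
within 10% (`apa_ratio`). A region call looks like:

```r
head(subset(res$starr$regions, class == "active"), 3)
#>    chrom start   end subset   combined_p          fdr rep_log2fc  class
#> 8   chrS 12375 12825    Th0 6.823115e-06 0.0001705779   1.912360 active
#> 12  chrS 18775 19225    Th0 1.725719e-05 0.0002688977   1.465006 active
#> 15  chrS 23575 24025    Th0 2.377382e-04 0.0016981298   1.432554 active
```

(`rep_log2fc ≈ 2` is the planted 4-fold activation.)

## Command-line entry points

Thin wrappers in `inst/cli/`: `starr-activity.R`, `specificity.R`,
`design-guides.R`, `screen-test.R` — each documents its flags at the top
of the file and reads/writes plain BED/TSV/JSON.
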