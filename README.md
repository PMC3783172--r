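# promenrich

In-silico promoter analysis of regulated gene sets, plus NanoString
nCounter-style count normalization — the computational workflow used to ask
"which cis-regulatory elements explain this expression response?" for
interferon-regulated (or any other) gene sets.

## What it does

**Motif scanning.** TRANSFAC-format position weight matrices are parsed and
matched against TSS-anchored promoter windows (default −600 bp to +100 bp,
both strands) with the matrix similarity score

    MSS = (Current − Min) / (Max − Min),
    Current = Σᵢ I(i) · f(i, wᵢ),   I(i) = Σ_b f(i,b) · ln(4 f(i,b)),

where `f(i, b)` are the matrix's base frequencies and `I(i)` the
per-position information weights; `Min`/`Max` are the worst/best attainable
scores, so MSS ∈ [0, 1]. A window is a hit when MSS ≥ 0.85 and the score
restricted to the 5-position maximal-information core is ≥ 0.99.

**Enrichment statistics.** For each matrix, per-promoter site counts in a
regulated foreground are compared with a random background by a two-sided
Mann–Whitney–Wilcoxon test; p-values are Benjamini–Hochberg corrected
across matrices. Enrichment is reported as `log2(d/b)` — the log fold-ratio
of mean sites per promoter (foreground `d` vs background `b`) — and a
matrix is called overrepresented when all of: ≥ 2-fold enrichment,
corrected P < 0.005, sites in ≥ 5 promoters and in ≥ 25% of the foreground.
Positional 200-bp-bin cumulative profiles over 20 kb upstream,
induction-strength cross-tabs and site-count cooperativity tests
(Spearman) complete the analysis.

**nCounter processing.** Per sample, the mean + 2 SD of the
negative-control counts is subtracted (clamped at 0); the 7 most stable
reference candidates (smallest CV of log counts) are selected; samples are
rescaled to equal reference geometric means. Repression is called at > 20%
reduction of treated vs mock means, and class-wise dependence is tested
with an exact two-sided Fisher test (minimum-likelihood enumeration).

**Synthetic data.** Every input format the pipeline reads (FASTA genome,
BED6 TSS table, TRANSFAC matrices, DE tables, count matrices) can be
generated with known ground truth, fully determined by a seed, so each
stage is verifiable end to end.

## Worked example

```r
library(promenrich)

## plant an ISRE-like motif at 2.0 sites/promoter into 60 foreground
## promoters vs 0.5 into 1000 background promoters, scan, and test
ex <- simulate_enrichment_experiment(seed = 1)
print(ex$result)
#> Motif enrichment: 1 matrices, window ( -600 , 100 ), 1 passing
#>  matrix_id n_fg genes_with_sites_fg pct_with_sites   d     b enrichment
#>   ISRE_SYN   60                  41           68.3 1.2 0.265       2.18
#>  enrichment_shrunk p_raw p_adj passes
#>               2.17 1e-18 1e-18   TRUE
```

The planted 4-fold density ratio is recovered (`enrichment` ≈ 2 =
log2(4)): per-instance detection is below 1 because instances are sampled
from the matrix's frequency rows, but the thinning applies to foreground
and background alike, leaving the ratio unbiased. The matrix passes all
four overrepresentation criteria.

```r
## the exact Fisher test on a 2x2 dependence table
fisher_exact(matrix(c(11, 8, 2, 19), 2, byrow = TRUE))$p.value
#> [1] 0.001890238
```

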