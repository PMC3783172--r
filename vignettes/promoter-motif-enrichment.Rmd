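---
title: "Promoter cis-regulatory element enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter cis-regulatory element enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promenrich)
```

This vignette is the package's own account of the statistical machinery it
implements: the scoring model, the enrichment test and its pass rules, the
positional and cooperativity summaries, the nCounter normalization recipe,
the synthetic-data generator that stands in for external downloads, and the
numerical and design choices made where the method left room.

## The scoring model

A binding-site model is a TRANSFAC-style count matrix: at each of its $L$
positions, counts over A, C, G, T that row-normalise to frequencies
$f(i,b)$. Matching is done with the information-weighted, min–max
normalised **matrix similarity score**

$$\mathrm{MSS}(w) \;=\; \frac{\mathrm{Current}(w) - \mathrm{Min}}
                             {\mathrm{Max} - \mathrm{Min}},\qquad
\mathrm{Current}(w) = \sum_{i=1}^{L} I(i)\, f(i, w_i),$$

with per-position information weights $I(i) = \sum_b f(i,b)\ln(4 f(i,b))$
(natural log, $0\ln 0 := 0$): $I=0$ for an uninformative uniform position
and $\ln 4$ for a fully determined one. `Min` and `Max` are the worst and
best attainable values of `Current`, so the score lives in $[0,1]$, equals
1 exactly on the consensus word and 0 on the anti-consensus. The **core
score** is the same quantity restricted to the 5 consecutive positions of
maximal summed information (leftmost on ties; matrices shorter than 5 use
all positions and are flagged). A window is a hit when its core score is at
least 0.99 *and* its full MSS at least 0.85 — the conventional stringent
threshold pair for this score family. Both strands are scanned; a
minus-strand hit is a match to the reverse complement, reported at the
window's start in gene orientation.

Numerical choices worth knowing:

* **No pseudocounts.** Scores are min–max normalised similarities, not
  log-odds, so zero frequencies are harmless; adding pseudocounts would
  only blur sharp matrices.
* **Non-ACGT characters.** Any window containing an `N` (or other
  ambiguity code) scores 0 — conservative, so masked sequence can never
  produce a hit.
* **Exact endpoint scores.** The scanner accumulates the attainable
  minimum and maximum in the same floating-point order as the window
  scores, so a consensus window scores exactly 1.0 (not within rounding
  of it); tests rely on this.
* **Overlaps.** Overlapping hits and same-offset opposite-strand hits are
  distinct sites; no collapsing rule is applied at the hit level.
* **Evaluation order.** Core score first, full MSS only at core-passing
  offsets — an optimisation with an identical result, since final hits
  must pass both thresholds anyway.

The score formula itself is a modelling choice: threshold conventions of
the 0.85/0.99 form are attached to this MATCH-style score family, and all
downstream statistics are defined relative to whichever scanner produced
the hit table, so a different scoring scheme can be substituted without
touching the statistics.

## Promoter windows

Promoters are TSS-anchored, gene-oriented windows, by default $(-600,
+100)$ in 0-based half-open TSS-relative coordinates where position 0 *is*
the TSS base and upstream is negative. For a minus-strand gene the window
is the reverse complement of the mirrored genomic slice, so the frame
always reads in transcription direction. Windows clipped at contig ends
are kept, flagged `truncated`, and scanned over their available sequence —
the per-promoter count statistic tolerates unequal lengths, and the
fraction-of-promoters criteria are per gene. (A configuration flag lets a
user exclude truncated promoters from the background instead; including
them is the default because there is no principled reason a short promoter
cannot be a background observation.)

Overlapping and redundant promoters are discarded, one record per gene: a
left-to-right sweep keeps a record only if its genomic window does not
overlap an already-kept one, so the survivor of an overlapping pair is the
record with the leftmost window start (ties by gene id). The survivor rule
is a tie-break of our choosing — any deterministic rule gives a pairwise
non-overlapping, one-per-gene universe, which is all the statistics need.

## The enrichment statistic

For one matrix, let $x_g$ be the number of hits in gene $g$'s window. The
foreground (regulated) counts are compared with the counts of randomly
chosen background promoters (default 1000, sampled without replacement
from the deduplicated universe minus the foreground) by a **two-sided
Mann–Whitney–Wilcoxon test**. Site counts are heavily tied, so the normal
approximation with tie-corrected variance is used; the exact distribution
is enumerated only when both sets have at most 8 genes and no ties occur.
The headline effect size is

$$\mathrm{enrichment} = \log_2(d/b),$$

$d$ and $b$ the mean sites per promoter in foreground and background. When
$b = 0$ the enrichment is undefined and the matrix can never pass — the
headline statistic is not inflated by a pseudocount; a shrunk diagnostic
$d/(b + 1/n_{bg})$ is reported separately for triage.

Across the matrix collection, raw p-values are Benjamini–Hochberg
adjusted, and a matrix is called **overrepresented** when all four hold:

1. enrichment $\geq 1$ (i.e. $\geq$ 2-fold),
2. adjusted $P < 0.005$,
3. sites in at least 5 foreground promoters,
4. sites in at least 25% of foreground promoters.

Highly redundant matrices (multiple TRANSFAC models of one factor) are
collapsed after testing: within each redundancy group the smallest
adjusted p survives. The default grouping — shared factor-name prefix of
the matrix id — is a heuristic for what is editorially a manual judgement;
a user-supplied mapping overrides it.

Two conventions were open and are fixed as follows. *Sidedness*: the test
is two-sided; direction is imposed downstream by the enrichment $\geq$
2-fold rule, so a one-sided test would only double-count the direction
constraint. *Background composition*: the background is a uniform random
gene sample; GC- or length-matched backgrounds are deliberately out of
scope, and the per-promoter fraction criteria partially absorb
composition effects.

## Positional profiles, cross-tabs, cooperativity

The **positional profile** extends scanning to 20 kb upstream: for bin
boundaries $D = 200, 400, \dots, 20000$ bp, the cumulative curve is the
fraction of genes with at least one site within $D$ bp upstream of the TSS
(downstream hits count at distance 0, so they appear from the first bin).
The difference curve foreground − background highlights where relative
enrichment accumulates. Cumulative curves are nondecreasing and bounded by
construction, and the difference of identical sets is identically zero —
both properties are tested.

The **strength/time cross-tab** reports, per time window and fold cut
(default $>2, >4, >8, >16$-fold), the percentage of induced genes whose
promoter carries at least one site of each element; empty strata are `NA`
with a warning rather than 0, since "no genes above 16-fold at this time"
is absence of evidence.

**Cooperativity** classes genes by site count (0, 1, >1) and reports class
medians of the log2 fold change, plus a two-sided Spearman rank
correlation between the *raw* site count and induction. Spearman was
chosen over Pearson to stay rank-based, consistent with the nonparametric
test above; when either variable is constant the correlation is reported
as 0 with $p = 1$ (no evidence of association, rather than an error).

The **per-gene normalization** of a log2 time-course matrix is row-mean
centering (each gene's curve shows deviation from its own average);
z-scoring is available behind a flag. The accompanying heat map is a thin
rendering utility — complete-linkage clustering of Euclidean distances —
and makes no tested statistical claim.

## nCounter processing

The normalization recipe, in order:

1. **Background correction.** Per sample, threshold = mean + 2 SD (sample
   SD, $n-1$) of the negative-control counts; subtracted from every gene,
   clamped at zero — counts are physical, so negatives are not propagated.
2. **Reference selection.** The 7 most stable of the candidate
   housekeeping genes, stability = coefficient of variation of
   $\log_2(\text{corrected}+1)$ across samples (ties by gene id). CV of
   log counts is the simplest defensible stability metric; pairwise
   geNorm-style stability is out of scope.
3. **Geometric-mean normalization.** Per sample, the geometric mean $g_s$
   of the reference counts; sample $s$ is rescaled by $\bar g / g_s$. The
   anchor $\bar g$ (mean of per-sample geomeans) keeps values on the
   original count scale; any anchor yields identical between-sample
   ratios, so this is cosmetic. Normalization is idempotent, and a global
   rescaling of one sample is absorbed exactly (within a run; across
   independent normalizations the anchor contributes one common factor).

**Repression calls** compare condition means over replicates: repressed
iff $(\bar x_{mock} - \bar x_{treated})/\bar x_{mock} > 0.20$; a zero mock
mean yields `NA` with a warning. The 20% default matches the reduction
threshold used in STAT1-dependence classification; it is configurable.

**Fisher's exact test** is implemented by full enumeration over tables
with the observed margins, summing all hypergeometric probabilities not
exceeding the observed one within relative tolerance $1 + 10^{-7}$ — the
minimum-likelihood two-sided convention. On the worked 2×2 example
(11/19 vs 2/21) it gives $P = 0.0019$ to four decimals, and it agrees with
an independent implementation to $10^{-9}$ over random tables.

## The synthetic-data generator

The generator emulates exactly the structure the statistics assume, so
that every stage can be verified against a ground-truth manifest:

* **Genomes / promoters**: i.i.d. bases at a stated GC content (default
  0.42, mammalian-like), TSSs spaced so neighbouring windows are disjoint
  whatever the strands, both strands represented.
* **Planted motifs**: per promoter a Poisson($\lambda$) number of
  instances sampled from the matrix's frequency rows, written at uniform
  (or TSS-proximal exponential, mean 2000 bp) offsets and random strands
  without overwriting other plants; the manifest records every instance.
  Poisson plants are the minimal structure under which the count test's
  null and alternative are well defined.
* **DE tables**: regulated genes $\log_2\mathrm{fc} \sim N(\pm
  \text{effect}, \sigma)$ with small adjusted p; nulls centred at 0 with
  p above the cutoff.
* **nCounter runs**: counts $= s_s\,(b_g\, e_{gs}\, \varepsilon) +
  \text{background}$, with log-normal noise $\varepsilon$ of stated CV,
  per-sample scale factors $s_s$, Poisson background (or Normal with a
  stated SD, so that SD $=0$ gives the deterministic zero-noise limit in
  which planted scales and repression fractions are recovered exactly).
  Counts are kept real-valued rather than rounded so that the zero-noise
  algebra is exact.

The default planted matrix is a sharp ISRE-like 12-mer (consensus base
frequency 0.91 per position). Instances sampled from its rows are detected
at the 0.85/0.99 thresholds with probability around 0.55 — deliberate,
since real sites are imperfect matches too. The detection thinning applies
equally to foreground and background plants, so the planted 4-fold density
ratio is recovered unbiasedly; the reference experiment (2.0 vs 0.5 sites
per promoter, 60 vs 1000 promoters) measures $\log_2(d/b) \approx 2$ and
passes all four criteria in essentially every replicate.

What the generator does **not** emulate: repeat structure, CpG islands,
GC/length heterogeneity between foreground and background, correlated
sites, isoform structure, probe-level array artefacts. Passing tests
therefore demonstrate the correctness of the statistical machinery under
its own assumptions, not robustness to real-genome composition effects —
on real data the uniform random background absorbs less composition bias
than a matched background would.

## Problem sizes and determinism

All stochastic steps take explicit seeds and are exactly reproducible.
The test and verification suites use: 1000 random (matrix, window) pairs
for scorer agreement (to $10^{-12}$); exhaustive enumeration of every
achievable rank-statistic value for set sizes up to 8 vs 8; 500 null
simulations (Poisson(1) counts, 50 vs 500 genes) for the empirical test
size; 100 replicates of the full sequence-level planted-motif experiment
(60 + 1000 promoters of 700 bp each per replicate); and 100-replicate
recovery suites for reference selection and repression calling. These
sizes give binomial standard errors small enough for 3-SD acceptance
bands while keeping a full verification run in the minutes range.

## Known limitations

* The MSS formula is a reconstruction of the score family its thresholds
  come from; absolute hit counts depend on it, though all downstream
  statistics are scanner-agnostic.
* The redundancy grouping heuristic (id prefix) under-groups matrices
  whose ids do not share a prefix; curated mappings should be supplied
  for serious use.
* The uniform random background does not control for GC content or
  promoter length.
* The repression-dependence classification threshold (20%) is a
  convention, not an estimate; conclusions near the threshold are
  fragile.
* `fisher_exact` enumerates the full support and is intended for the
  small tables of targeted panels, not genome-scale contingency tables.
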