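---
title: "Annotating developmental methylomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating developmental methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`methsuite` turns per-cytosine bisulfite-sequencing count tables into the
feature set that characterises a developing tissue's methylome:
methylation levels corrected for incomplete bisulfite conversion,
differentially methylated sites (DMSs) and regions (CG-DMRs),
tissue-specific hypomethylation, loss/gain-of-mCG event accounting, large
hypomethylated blocks, DNA methylation valleys (DMVs), partially
methylated domains (PMDs) and non-CpG methylation (mCH) domains, plus the
enrichment statistics used to interpret them. Because genome-scale ground
truth does not exist for real tissue, the package ships a synthetic
methylome generator whose planted features are recorded exactly, so every
caller is validated by recovery against truth rather than by eyeballing.

# The measurement model

A whole-genome bisulfite experiment reports, per cytosine and strand, a
methylated basecall count `mc` and total count `cov`. The methylation
level of a site or region is

    level = max(0, sum(mc) / sum(cov) - r)

where `r` is the bisulfite **non-conversion rate**, estimated as the
methylated fraction of an unmethylated lambda phage spike-in. Two
conventions matter and are used everywhere:

* **Regions pool counts.** A region's level is the count-weighted mean of
  its sites' raw fractions minus `r`, never the mean of per-site levels.
  Sites with deeper coverage therefore carry more weight, which is the
  behaviour of the ratio estimator the field uses.
* **Clamping at zero.** Subtracting `r` can produce slightly negative
  values at unmethylated sites; these are clamped to 0. Zero-coverage
  sites yield `NA`, never 0 — "no data" and "unmethylated" are different
  statements.

CpG dyads are measured on both strands; `merge_strand_cg()` collapses the
(+, p) / (−, p+1) pair into one record at p with counts summed, which
halves the variance of per-site CpG estimates and is assumed by every CG
caller downstream. QC per sample comprises mean coverage (strand-combined
for CpG), the non-conversion rate, and the Pearson correlation of per-site
mCG fractions between replicates at sites with at least 10 reads in both.

# DMS and CG-DMR calling

The DMS test asks, per strand-merged CpG site, whether the per-sample
methylated fractions are more dispersed than read sampling alone allows.
The statistic is a coverage-standardised root-mean-square deviation in
chi-square form,

    T = sum_s cov_s * (f_s - fbar)^2 / (fbar * (1 - fbar)),

with `fbar` the pooled fraction. Its null distribution comes from
permutation: methylated read labels are re-allocated across samples by
sequential multivariate hypergeometric draws, preserving each sample's
coverage and the site's methylated total. Because the statistic is
standardised, permuted values are pooled **across sites**, giving p-value
resolution `1 / (n_sites * n_perm + 1)` (default `n_perm = 100`); with
per-site permutations alone the smallest attainable p-value, `1/(B+1)`,
can never clear a Benjamini–Hochberg cutoff across tens of thousands of
sites, so genome-scale FDR control would be structurally impossible. The
pooled null assumes the standardised statistic is comparable across
coverage profiles, which holds to the accuracy the chi-square
approximation does; the test is deliberately a documented, configurable
stand-in, since the upstream caller it emulates is defined by software
rather than by a printed formula.

DMSs merge into CG-DMRs when within 250 bp of the previous DMS and
pattern-compatible, defined as intersecting hypo-sample sets (a DMS's hypo
set is the samples more than 0.1 below the across-sample mean fraction).
"Similar sample-specific patterns" has no printed definition, so the
intersection rule is this package's explicit, configurable choice. Blocks
with fewer than three DMSs are dropped.

## Tissue specificity: the bulk baseline

Hypomethylation needs a baseline. For each region with per-sample levels
`x_1 … x_N` (liver excluded; regions with any zero-coverage sample
dropped), the levels are sorted and the narrowest window of `ceiling(N/2)`
consecutive ordered values is found; its mean `b` is the baseline, and
samples with `x_s − b ≤ −0.3` form the hypo set. Window ties break to the
smallest starting index and equal levels keep sample order (stable sort),
so the result is deterministic. The **effect size** is `|min(x) − b|`. A
brute-force enumeration of all windows is kept in the test suite as an
oracle. Loss- and gain-of-mCG events are counted per consecutive-stage
interval with threshold 0.1: a region contributes at most one loss and one
gain per interval.

CG-DMR categories follow a fixed priority: CGI promoter, non-CGI promoter,
CGI, CGI shore (proximal tiers, promoters being TSS ± 2.5 kb and shores
CGI ± 2 kb), then for distal regions: enhancer score > 0.3 (strict) makes
a distal feDMR, within 1 kb of one makes a flanking distal feDMR,
tissue-specific hypomethylation (effect ≥ 0.3) makes a primed distal
feDMR, and the remainder split into te-/nte-unxDMRs by transposon overlap.
Enhancer scores are an optional input column — computing them is outside
this package's scope — and when absent the feDMR tier is skipped with a
warning.

# Domain callers

**Large hypo blocks** merge a tissue's tissue-specific CG-DMRs within 1 kb
and keep blocks of at least 2 kb.

**DMVs** work on 1-kb binned mCG tracks: runs of bins below 0.15, where
no-data bins (no sites or no reads) are skipped — they neither break the
run nor count toward the five-with-data-bin minimum. Whether a run may
span arbitrarily long no-data stretches is genuinely open; the default is
unlimited with a configurable `max_gap_bins`. A DMV must be reproduced
across replicates (blocks of either replicate overlapping one of the
other, then merged).

**PMDs** are classified, not thresholded: per 10-kb bin, the 5th–95th
percentiles in steps of 5 (19 features) of per-site methylation fractions
feed a random forest. Sites inside CGIs, DMVs or Hox-like exclusion loci
and sites under 5 reads are excluded first; bins with fewer than 10
remaining sites are unclassifiable. The percentile grid is a design
choice — only "percentiles" is specified by the approach this follows —
and the forest defaults to 1,000 trees (10,000, the full-fidelity
setting, is available via `ntree`; on the packaged data the out-of-bag
error is flat well below 1,000). Predicted bins merge, blocks under
100 kb or overlapping assembly gaps are dropped, replicate calls are
intersected, and Hox-overlapping calls removed. On synthetic data the
training labels come from the truth manifest; on real data they would come
from manually curated example regions.

**mCH domains** use penalised change-point segmentation of 5-kb mCH
tracks (bins need ≥ 500 CH sites with ≥ 50% covered by ≥ 10 reads).
`pelt_segment()` is an exact pruned dynamic programme for the squared
-error cost with a per-changepoint penalty and a minimum segment length of
2; the unpruned O(n²) optimal-partitioning recursion is kept as a test
oracle. Levels are scaled by 1,000 before segmentation and the default
penalty is `2·max(σ̂², 1)·log(n)` with σ̂ from the median absolute
deviation of first differences. The unit-variance floor matters: control
samples are nearly flat, a purely data-driven σ̂ is then tiny, and the
segmenter would shatter artefact regions into interior chunks whose
neighbours are equally artefactual, letting them evade the elevation rule
below. The floor encodes the convention that motivates the ×1,000
scaling in the first place. The penalty a specific R changepoint
configuration would imply is not re-derived; equivalence is not claimed,
and the penalty is exposed in the configuration.

A chunk is a domain candidate when its level is at least 1.5× that of
both neighbouring chunks (pseudo-level 0.001 in the denominator; terminal
chunks have one neighbour and are never called). The caller iterates over
**control samples** — early-stage samples with no genuine mCH — adding
their domain candidates to an exclusion list and re-segmenting with
excluded bins ignored, until the list stops growing; since the list only
grows, termination is guaranteed on a finite genome, with an iteration cap
for diagnostics. All samples are then segmented the same way, per-
(tissue, stage) calls must appear in both replicates, sub-15-kb or
sub-3-bin regions are dropped, and per-tissue calls merge into the final
list. Domain profiles for clustering are length-50 vectors (20 upstream
5-kb bins, 10 equal body divisions, 20 downstream) divided by the flank
mean, with k-means at fixed seed; the repression contrast z-scores each
gene's expression across a tissue's stages and reports domain genes minus
non-domain genes per stage, which is negative when domain genes shut down.
The subtraction is oriented so that the value reads as "expression of
domain genes relative to the rest".

# Enrichment statistics

The motif test is the upper-tail hypergeometric probability of observing
at least `n_f` item-overlapping foreground regions among `N_f` foreground
and `N_b` background regions, after both sets are symmetrically extended
to a common mean width of 400 bp (extension only — sets already wider are
left alone); BH correction runs across items, and items whose TF falls
under 10 TPM can be filtered. The Monte-Carlo overlap test re-places the
feature set uniformly in the gap-free genome (length-preserving, features
entirely within one gap-free stretch, overlaps among shuffled features
allowed — the dialect of the common shuffling tools) and uses
`p = (Σ I(x_obs ≤ x_i) + 1)/(k + 1)`, inclusive on ties, with fold
enrichment `x_obs / mean(x_i)`; both a feature-count and a base-pair
statistic are offered because printed fold enrichments do not always say
which was used. The gene-set test draws `|query|` genes without
replacement from the universe. All permutation statistics are retained on
the result object for audit.

# The synthetic methylome and what it does (and does not) show

The generator emulates the statistical structure of a multi-tissue
developmental WGBS study at desk scale. The packaged configuration — the
study conditions for all tests — is a 5-Mb genome (3 + 2 Mb), CpG dyads at
1 per 100 bp, CH sites at 0.12 per bp, three tissues (forebrain, heart,
liver) × four stages (E10.5, E13.5, E16.5, P0) × two replicates, mean
coverage 30 reads per strand position (Poisson; the depth distribution is
unspecified in the source material, and Poisson is the standard neutral
choice), and non-conversion 0.005 acting only on unmethylated cytosines
(observed probability `m + (1−m)·r`, the chemistry of failed conversion).
Counts are Binomial given coverage. Per-sample seeds derive from one
master seed; regeneration is byte-identical.

Planted features: 20 tissue-specific CG-DMRs (600–1,500 bp, placed only
where local CpG spacing can support a ≥ 3-DMS block at the 250-bp merge
distance — DMRs in CpG deserts are undetectable by construction, and real
regulatory DMRs sit in CpG-adequate sequence) with piecewise-linear
trajectories from 0.85 down to 0.15, a 30% subset regaining +0.5 at the
final stage (postnatal remethylation); six DMVs (5–10 kb at 0.05, all
samples); two liver PMDs (300 and 500 kb at 0.5); five mCH domains
(25–50 kb, 2× the stage background of 0.002/0.005/0.010/0.015); and three
artefact regions with mCH 0.04 in **every** sample, controls included,
emulating mapping artefacts — these exist so the exclusion loop has real
work to do. Trajectory values were chosen so that true baseline
differences stay ≥ 0.067 away from the ±0.3 hypo decision boundary; at
the packaged coverage that is > 4 standard errors, so exact hypo-set
recovery is a property of the method rather than a coin flip. Outside
planted features, per-CpG background levels are heterogeneous (CGI sites
at 0.05, others jittered around 0.85 with s.d. 0.08, truncated to
[0.6, 0.98], shared across samples): a perfectly flat background would
make replicate correlation noise-dominated, whereas real methylomes have
strong between-site variance; with heterogeneity the replicate r of
~0.87–0.92 matches the regime real tissue samples are accepted at.

What passing recovery tests does **not** show: the generator has
homogeneous cell populations (an optional mixture knob exists but the
packaged conditions do not use it), no sequence-level realism beyond
context labels, no read-level errors or mapping biases beyond the planted
artefact regions, independent sites (no local autocorrelation of
methylation state beyond the planted features), and effect sizes chosen
to be detectable at 30×. Perfect recovery here demonstrates correctness
of the algorithms and their wiring, not expected performance on real
tissue, where boundary effects, intermediate cell mixtures and mappability
artefacts will erode every metric.

# Numerical choices and degenerate inputs

* Window-argmin ties in the bulk baseline break to the smallest index;
  which.min's first-minimum semantics implement this directly, and
  floating-point "ties" are resolved by exact comparison.
* `cov = 0` yields `NA` levels (undefined, never 0); zero-length series
  and empty interval sets return empty, typed results.
* The binomial mCH test refuses `r = 0` — the null degenerates — and the
  caller must supply a floor (the pipeline uses `max(r̂, 1e-4)`).
* k-means (DMR trajectories, mCH profiles) runs with a fixed seed and 20
  restarts; it needs `k < n`, so the pipeline clusters only when at least
  three domains exist.
* BED intervals are 0-based half-open; allc positions 1-based; the
  conversion lives in one pair of helpers. Interval algebra is delegated
  to GenomicRanges behind those helpers, and the Monte-Carlo loop uses a
  sorted binary-search overlap path cross-checked against the
  GenomicRanges route and a naive per-base oracle.
* Problem sizes in the tests: oracle checks run at n ≤ 200 (segmentation)
  and N ≤ 12 (baseline windows); null calibration uses 10⁴ regions and
  500 shuffle runs at k = 200; the recovery check runs the full 5-Mb,
  24-sample pipeline. These sizes were chosen so the whole suite documents
  itself in minutes on a laptop while still exercising every code path at
  the packaged study scale.

# Known limitations

The DMS test and the merge-compatibility rule are documented stand-ins
for an external caller's behaviour; the segmentation penalty is defined
within this package rather than matched to any specific external default;
5mC and 5hmC are not distinguished (the assay cannot); enhancer-score
computation, motif scanning, super-enhancer calling and comparisons
against external replication-timing or lamina-association data are out of
scope — their inputs are consumed as plain tables where relevant.
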