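# methsuite

Feature annotation of multi-tissue developmental methylomes, from
per-cytosine bisulfite counts to the full catalogue of methylome
features, with a planted-truth synthetic data generator so that every
caller is validated by recovery rather than by inspection.

## Who this is for

Epigenomics analysts working with whole-genome bisulfite sequencing
(WGBS) of tissues across developmental stages, who need the standard
feature set of such studies as tested, composable R functions:

* **Methylation levels** with bisulfite non-conversion correction:
  `level = max(0, Σmc/Σcov − r)`, counts pooled before dividing, `r`
  estimated from an unmethylated lambda spike-in; CpG dyads strand-merged.
* **DMSs / CG-DMRs** — per-site dispersion test
  `T = Σ_s cov_s (f_s − f̄)² / (f̄(1−f̄))` against a pooled permutation
  null (multivariate hypergeometric read re-allocation), BH-controlled;
  DMSs merge into CG-DMRs within 250 bp under compatible hypo-sample
  patterns, three DMSs minimum.
* **Tissue-specific hypomethylation** by a bulk-baseline outlier rule:
  with ordered levels `x_(1) ≤ … ≤ x_(N)`, the baseline
  `b = mean of the narrowest window of ⌈N/2⌉ consecutive ordered values`,
  hypo samples `{s : x_s − b ≤ −0.3}`, effect size `|min(x) − b|`.
* **Loss/gain-of-mCG events** per consecutive-stage interval (threshold
  0.1), and CG-DMR categories (CGI promoter > non-CGI promoter > CGI >
  CGI shore > distal feDMR > flanking > primed > te-/nte-unxDMR).
* **Domains** — large hypo blocks (merge ≤ 1 kb, keep ≥ 2 kb); DMVs
  (≥ 5 with-data 1-kb bins < 0.15, replicate-reproducible); PMDs
  (random forest on 19 per-bin methylation percentiles, ≥ 100 kb, both
  replicates); mCH domains (exact PELT mean-shift segmentation of 5-kb
  mCH tracks, chunks ≥ 1.5× both neighbours, iterative exclusion of
  regions that misbehave in mCH-free control samples, ≥ 15 kb / 3 bins).
* **Enrichment** — upper-tail hypergeometric motif tests with BH
  correction and 400-bp size normalisation; Monte-Carlo shuffle tests
  with `p = (Σ I(x_obs ≤ x_i) + 1)/(k + 1)`; gene-set resampling tests.
* **Synthetic methylomes** — a 5-Mb, 3-tissue × 4-stage × 2-replicate
  design at 30× with planted DMRs, DMVs, PMDs, mCH domains and mapping
  artefacts, all recorded in a machine-readable truth manifest.

The methods vignette (`vignettes/methylome-features.Rmd`) documents the
models, parameter defaults, numerical choices and limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
packaged synthetic dataset (set `METHSUITE_SEED` to change the seed):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_dmr_calling.R
Rscript analysis/03_domains.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_recovery.R
```

At the default seed these print, among other things:

```
Coverage 32.3-32.3x; non-conversion 0.500-0.500%; replicate r 0.875-0.924
288 DMSs merged into 26 CG-DMRs (>= 3 DMSs within 250 bp, compatible hypo patterns)
26 CG-DMRs are tissue-specific at the 0.3 hypomethylation margin; median effect size 0.69
Methylation dynamics: 92% of events are loss-of-mCG; gains appear in the
  final (postnatal) interval
2 large hypo CG-DMR blocks (>= 2 kb after 1-kb merging)
6 DMVs (>= 5 with-data 1-kb bins under mCG 0.15, replicate-reproducible)
2 PMDs (>= 100 kb, random forest on per-bin methylation percentiles, both replicates)
5 mCH domains after 2 exclusion iterations (3 artefact regions excluded via control samples)
Genes inside mCH domains are repressed late in development: relative z at
  the final stage is -1.09 to -0.95 across tissues
Top motif: motifA (n_f = 11/13 foreground vs n_b = 0/13 background, p = 1.01e-05)
Recovery at seed 1: DMR hypo sets 100%, DMV Jaccard 1.000, PMD Jaccard 1.000,
  mCH recall/precision 1.00/1.00, 0 bases of mCH calls in artefact regions.
```

Read: every planted tissue-specific CG-DMR was recovered with exactly the
right hypomethylated sample set; the domain callers reproduce the planted
DMVs/PMDs/mCH domains at base-level Jaccard 1.0; the mCH exclusion loop
caught all planted mapping artefacts using only the mCH-free control
samples; and the event accounting shows the prenatal-demethylation /
postnatal-remethylation pattern (90% of events are losses).

In code, the same run is three calls:

```r
library(methsuite)
run <- run_pipeline(default_config(seed = 1))
score_recovery(run)
```

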