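#!/usr/bin/env Rscript
# Enrichment statistics: hypergeometric motif enrichment of one tissue's
# specific CG-DMRs against the other's, the Monte-Carlo shuffle test of
# DMR/transposon overlap, and the Monte-Carlo gene-set test for genes in
# mCH domains.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

run <- get_run(c("simulate", "dmr", "domains", "enrich"))

if (!is.null(run$motif_enrichment)) {
  put_tsv(run$motif_enrichment, "motif_enrichment.tsv")
  top <- run$motif_enrichment[order(p)][1]
  message(sprintf(
    "Top motif: %s (n_f = %d/%d foreground vs n_b = %d/%d background, p = %.3g, BH-adjusted %.3g)",
    top$item, top$n_f, top$N_f, top$n_b, top$N_b, top$p, top$p_adj))
}

if (!is.null(run$te_overlap)) {
  r <- run$te_overlap
  put_tsv(data.table(observed = r$observed,
                     mean_permuted = mean(r$permuted),
                     fold = r$fold, p = r$p, k = length(r$permuted)),
          "te_overlap.tsv")
  message(sprintf(
    "%s/transposon overlap: observed %d vs %.1f expected under shuffling (fold %.2f, p = %.3g)",
    run$te_overlap_regions, r$observed, mean(r$permuted), r$fold, r$p))
}

if (!is.null(run$tf_geneset)) {
  g <- run$tf_geneset
  message(sprintf(
    "TF-encoding genes among mCH-domain genes: observed %d, fold %.2f, p = %.3g",
    g$observed, g$fold, g$p))
}
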