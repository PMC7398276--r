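#!/usr/bin/env Rscript
# Call the large-scale methylome features: merged large hypo CG-DMR
# blocks, DNA methylation valleys, random-forest PMDs in the liver-like
# tissue, and mCH domains via iterative change-point segmentation with
# control-sample artefact exclusion.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

run <- get_run(c("simulate", "dmr", "domains"))

lh <- rbindlist(run$large_hypo, idcol = "tissue")
put_tsv(lh, "large_hypo.tsv")
message(nrow(lh), " large hypo CG-DMR blocks (>= 2 kb after 1-kb merging)")

put_tsv(run$dmvs, "dmvs.bed")
message(nrow(run$dmvs), " DMVs (>= 5 with-data 1-kb bins under mCG 0.15, ",
        "replicate-reproducible)")

put_tsv(run$pmds, "pmds.bed")
message(nrow(run$pmds), " PMDs (>= 100 kb, random forest on per-bin ",
        "methylation percentiles, both replicates)")

put_tsv(run$mch$domains, "mch_domains.bed")
put_tsv(run$mch$excluded, "mch_excluded.bed")
message(nrow(run$mch$domains), " mCH domains after ", run$mch$iterations,
        " exclusion iterations (", nrow(run$mch$excluded),
        " artefact regions excluded via control samples)")

if (!is.null(run$repression)) {
  put_tsv(run$repression, "repression_z.tsv")
  late <- run$repression[stage == tail(unique(stage), 1)]
  message(sprintf(
    "Genes inside mCH domains are repressed late in development: relative z at the final stage is %.2f to %.2f across tissues.",
    min(late$relative_z), max(late$relative_z)))
}
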