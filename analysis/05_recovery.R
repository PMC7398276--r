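#!/usr/bin/env Rscript
# Score every caller against the generator's planted truth: exact
# hypo-sample-set recovery for tissue-specific CG-DMRs, base-level Jaccard
# for DMVs and PMDs, and domain-level recall/precision for mCH domains.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

run <- get_run(c("simulate", "dmr", "domains"))
sc <- score_recovery(run)

tab <- data.table(
  metric = c("dmr_hypo_set_recovery", "dmv_base_jaccard", "pmd_base_jaccard",
             "mch_domain_recall", "mch_domain_precision",
             "mch_artefact_overlap_bases"),
  value = c(sc$dmr_hypo_recovery, sc$dmv_jaccard, sc$pmd_jaccard,
            sc$mch_recall, sc$mch_precision, sc$mch_artefact_bases))
put_tsv(tab, "recovery.tsv")

message(sprintf(
  "Recovery at seed %d: DMR hypo sets %.0f%%, DMV Jaccard %.3f, PMD Jaccard %.3f, mCH recall/precision %.2f/%.2f, %d bases of mCH calls in artefact regions.",
  SEED, 100 * sc$dmr_hypo_recovery, sc$dmv_jaccard, sc$pmd_jaccard,
  sc$mch_recall, sc$mch_precision, sc$mch_artefact_bases))
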