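# Orchestration: a single validated configuration drives
# simulate -> qc -> sitestats -> dmr -> domains -> enrich on the synthetic
# dataset, with deterministic seeding throughout and a run manifest of
# outputs and checksums. The analysis scripts under analysis/ are thin
# drivers over these functions.

#' Default run configuration
#'
#' All thresholds of the pipeline in one place, each overridable. The
#' defaults are the study conditions: a 5-Mb two-chromosome genome, three
#' tissues (forebrain, heart, liver) at four stages with two replicates,
#' ~30x coverage and 0.5% non-conversion.
#'
#' @param seed master seed; all stage seeds derive from it
#' @return nested named list of class `RunConfig`
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    genome = list(chrom_lengths = c(chr1 = 3e6, chr2 = 2e6),
                  cg_density = 0.01, ch_density = 0.12,
                  n_genes = 40, n_transposons = 400,
                  gap_length = 50000, n_hox_like = 2),
    design = list(tissues = c("forebrain", "heart", "liver"),
                  stages = c("E10.5", "E13.5", "E16.5", "P0"),
                  replicates = 2, coverage_mean = 30,
                  nonconversion_rate = 0.005),
    truth = list(),
    exclude_tissues_dmr = "liver",
    thresholds = list(
      hypo_margin = 0.3,
      event_delta = 0.1,
      dms_gap = 250, min_dms = 3, dms_fdr = 0.01, dms_n_perm = 100,
      dms_hypo_delta = 0.1,
      dmv_bin = 1000, dmv_threshold = 0.15, dmv_min_bins = 5,
      pmd_bin = 10000, pmd_min_len = 1e5, pmd_cov_min = 5,
      pmd_min_sites = 10, pmd_ntree = 1000,
      mch_bin = 5000, mch_min_sites = 500, mch_min_cov_frac = 0.5,
      mch_cov_threshold = 10, mch_min_len = 15000, mch_min_bins = 3,
      mch_elevation = 1.5, mch_pseudo = 0.001,
      enhancer_cutoff = 0.3, extend_width = 400,
      k_permutations = 1000,
      qc_cov_min = 10)),
    class = "RunConfig")
}

#' Validate a run configuration
#'
#' @param config a `RunConfig` (or plain list with the same shape)
#' @return the config, invisibly; stops with a message on the first
#'   invalid entry
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(th$hypo_margin > 0 && th$hypo_margin <= 1,
      "hypo_margin must be in (0, 1]")
  chk(th$event_delta > 0, "event_delta must be positive")
  chk(th$dms_gap >= 0, "dms_gap must be >= 0")
  chk(th$min_dms >= 1, "min_dms must be >= 1")
  chk(th$dms_fdr > 0 && th$dms_fdr < 1, "dms_fdr must be in (0, 1)")
  chk(th$dmv_threshold > 0 && th$dmv_threshold < 1,
      "dmv_threshold must be in (0, 1)")
  chk(th$dmv_min_bins >= 1, "dmv_min_bins must be >= 1")
  chk(th$pmd_min_len > 0, "pmd_min_len must be positive")
  chk(th$mch_elevation >= 1, "mch_elevation must be >= 1")
  chk(th$mch_pseudo > 0, "mch_pseudo must be positive")
  chk(th$enhancer_cutoff >= 0 && th$enhancer_cutoff <= 1,
      "enhancer_cutoff must be in [0, 1]")
  chk(th$k_permutations >= 1, "k_permutations must be >= 1")
  chk(config$design$coverage_mean > 0, "coverage_mean must be positive")
  chk(config$design$nonconversion_rate >= 0 &&
        config$design$nonconversion_rate < 0.05,
      "nonconversion_rate must be in [0, 0.05)")
  invisible(config)
}

# synthetic companion expression table: one TPM column per
# (tissue, stage); genes overlapping planted mCH domains decline with
# stage, mirroring repression of genes inside accumulating mCH domains
simulate_expression <- function(genome, truth, seed) {
  set.seed(seed)
  genes <- genome$annotations$gene_bodies
  n <- nrow(genes)
  in_domain <- bed_overlaps_any(genes, truth$mch_domains)
  base <- exp(rnorm(n, 3, 1))
  base[seq_len(n) %% 10 == 0] <- 0          # some silent genes
  meta <- unique(truth$design[, .(tissue, stage, stage_index)])
  meta[, sample_id := paste(tissue, stage, sep = "_")]
  n_stage <- max(meta$stage_index)
  tpm <- matrix(0, n, nrow(meta), dimnames = list(genes$gene, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    f <- ifelse(in_domain,
                1 - 0.6 * (meta$stage_index[j] - 1) / (n_stage - 1), 1)
    tpm[, j] <- base * f * exp(rnorm(n, 0, 0.1))
  }
  list(tpm = tpm, meta = meta, domain_genes = genes$gene[in_domain])
}

# synthetic motif occurrence tracks: motifA is planted preferentially in
# forebrain-hypo DMRs, motifB is uniform background
simulate_motif_occurrences <- function(genome, truth, seed) {
  set.seed(seed)
  fb <- truth$dmrs[hypo_tissue == unique(truth$dmrs$hypo_tissue)[1]]
  centre <- (fb$start + fb$end) %/% 2
  planted <- data.table(chrom = fb$chrom, start = centre - 5, end = centre + 5)
  rand_bed <- function(n) {
    cn <- sample(names(genome$chrom_lengths), n, replace = TRUE,
                 prob = genome$chrom_lengths)
    s <- vapply(cn, function(c) sample.int(genome$chrom_lengths[[c]] - 10, 1),
                numeric(1))
    data.table(chrom = cn, start = s, end = s + 10)
  }
  list(motifA = rbind(planted[seq_len(ceiling(nrow(planted) * 0.8))],
                      rand_bed(200)),
       motifB = rand_bed(200))
}

#' Run the full synthetic-methylome analysis pipeline
#'
#' Stages: `simulate` (genome, truth, per-sample counts, per-sample QC and
#' level tracks), `dmr` (DMS and CG-DMR calling, tissue-specific baseline,
#' events, categories), `domains` (large hypo blocks, DMVs, PMDs, mCH
#' domains, profiles, repression z-scores), `enrich` (motif hypergeometric
#' test, transposon-overlap Monte-Carlo test, TF gene-set test). Later
#' stages require the earlier ones; results accumulate in the returned
#' run object. With `outdir`, every stage writes its tables plus a JSON
#' run manifest with per-file checksums.
#'
#' @param config a validated `RunConfig`
#' @param stages subset of c("simulate", "dmr", "domains", "enrich")
#' @param outdir optional output directory
#' @param quiet suppress progress messages
#' @return a `run` list with all results
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "dmr", "domains", "enrich"),
                         outdir = NULL, quiet = FALSE) {
  validate_config(config)
  th <- config$thresholds
  say <- function(...) if (!quiet) message(...)
  run <- list(config = config)

  stages <- match.arg(stages, c("simulate", "dmr", "domains", "enrich"),
                      several.ok = TRUE)
  need <- function(stage, field)
    if (is.null(run[[field]]))
      stop("stage '", stage, "' requires the 'simulate' stage first")

  ## ------------------------------------------------------------------ ##
  if ("simulate" %in% stages) {
    say("simulate: genome + truth + ", "counts per sample")
    run$genome <- do.call(generate_genome,
                          c(config$genome, list(seed = config$seed)))
    design <- do.call(make_design, config$design)
    run$truth <- plant_truth(run$genome, design,
                             c(config$truth, list(seed = config$seed + 7)))
    run$design <- run$truth$design

    cg_sites <- list(); ch_tracks <- list(); cg_tracks <- list()
    qc <- list(); lambda_sums <- list(); mch_sig <- list()
    for (i in seq_len(nrow(design))) {
      smp <- as.list(design[i])
      sim <- simulate_counts(run$genome, run$truth, smp,
                             seed = (config$seed * 1009L + i * 101L) %%
                               .Machine$integer.max)
      r_hat <- sum(sim$lambda$mc) / sum(sim$lambda$cov)
      lambda_sums[[smp$sample_id]] <- c(mc = sum(sim$lambda$mc),
                                        cov = sum(sim$lambda$cov))
      is_cg <- substr(sim$allc$context, 1, 2) == "CG"
      cg_sites[[smp$sample_id]] <- merge_strand_cg(sim$allc[is_cg])
      ch <- sim$allc[!is_cg]
      qc[[smp$sample_id]] <- list(
        mean_coverage = mean(c(cg_sites[[smp$sample_id]]$cov, ch$cov)),
        nonconversion_rate = r_hat,
        global_mcg = region_level(cg_sites[[smp$sample_id]], r_hat),
        global_mch = region_level(ch, r_hat))
      cg_tracks[[smp$sample_id]] <- binned_levels(
        cg_sites[[smp$sample_id]], th$dmv_bin, run$genome$chrom_lengths,
        nonconversion = r_hat, context = "CG")
      ch_tracks[[smp$sample_id]] <- binned_levels(
        ch, th$mch_bin, run$genome$chrom_lengths, nonconversion = r_hat,
        min_sites = th$mch_min_sites,
        min_covered_fraction = th$mch_min_cov_frac,
        cov_threshold = th$mch_cov_threshold, context = "CH")
      sig <- mch_site_test(ch, max(r_hat, 1e-4))
      mch_sig[[smp$sample_id]] <- sum(sig$sites$significant)
      rm(sim, ch); gc(FALSE)
    }
    run$cg_sites <- cg_sites
    run$cg_tracks <- cg_tracks
    run$ch_tracks <- ch_tracks
    run$lambda_sums <- lambda_sums
    # replicate concordance per (tissue, stage)
    qc_dt <- rbindlist(lapply(names(qc), function(id)
      c(list(sample_id = id), qc[[id]],
        list(n_mch_significant = mch_sig[[id]]))))
    pairs <- design[, .(ids = list(sample_id)), by = .(tissue, stage)]
    qc_dt[, replicate_r := NA_real_]
    for (i in seq_len(nrow(pairs))) {
      ids <- pairs$ids[[i]]
      if (length(ids) < 2) next
      a <- cg_sites[[ids[1]]]; b <- cg_sites[[ids[2]]]
      ab <- merge(a[, .(chrom, pos, mc1 = mc, cov1 = cov)],
                  b[, .(chrom, pos, mc2 = mc, cov2 = cov)],
                  by = c("chrom", "pos"))
      ab <- ab[cov1 >= th$qc_cov_min & cov2 >= th$qc_cov_min]
      r <- if (nrow(ab) >= 2) cor(ab$mc1 / ab$cov1, ab$mc2 / ab$cov2) else NA
      qc_dt[sample_id %in% ids, replicate_r := r]
    }
    run$qc <- qc_dt
    run$expression <- simulate_expression(run$genome, run$truth,
                                          config$seed + 11)
  }

  ## ------------------------------------------------------------------ ##
  if ("dmr" %in% stages) {
    need("dmr", "cg_sites")
    say("dmr: DMS calling + CG-DMR merging + tissue specificity")
    design <- run$design
    keep <- design[!tissue %in% config$exclude_tissues_dmr]
    groups <- unique(keep[order(tissue, stage_index),
                          .(tissue, stage, stage_index)])
    groups[, id := paste(tissue, stage, sep = "_")]
    run$dmr_samples <- groups
    # replicate-combined site count matrices
    template <- run$cg_sites[[keep$sample_id[1]]][, .(chrom, pos)]
    mc <- matrix(0L, nrow(template), nrow(groups))
    cov <- matrix(0L, nrow(template), nrow(groups))
    r_hat <- numeric(nrow(groups))
    for (j in seq_len(nrow(groups))) {
      ids <- keep[tissue == groups$tissue[j] & stage == groups$stage[j],
                  sample_id]
      for (id in ids) {
        s <- run$cg_sites[[id]]
        mc[, j] <- mc[, j] + s$mc
        cov[, j] <- cov[, j] + s$cov
      }
      lam <- Reduce(`+`, run$lambda_sums[ids])
      r_hat[j] <- lam["mc"] / lam["cov"]
    }
    colnames(mc) <- colnames(cov) <- groups$id
    run$dms <- call_dms(mc, cov, template$chrom, template$pos,
                        n_perm = th$dms_n_perm, fdr = th$dms_fdr,
                        hypo_delta = th$dms_hypo_delta,
                        seed = config$seed + 23)
    run$dmrs <- merge_dms_to_dmrs(run$dms, max_gap = th$dms_gap,
                                  min_dms = th$min_dms)
    say("dmr: ", sum(run$dms$is_dms), " DMSs -> ", nrow(run$dmrs),
        " CG-DMRs")
    # per-DMR per-sample pooled levels
    lev <- matrix(NA_real_, nrow(run$dmrs), nrow(groups),
                  dimnames = list(NULL, groups$id))
    if (nrow(run$dmrs)) {
      idx <- point_interval_index(template$chrom, template$pos, run$dmrs)
      for (j in seq_len(nrow(groups))) {
        msum <- tapply(mc[!is.na(idx), j], idx[!is.na(idx)], sum)
        csum <- tapply(cov[!is.na(idx), j], idx[!is.na(idx)], sum)
        lev[as.integer(names(msum)), j] <-
          methylation_level(as.numeric(msum), as.numeric(csum), r_hat[j])
      }
    }
    run$dmr_levels <- lev
    run$tissue_specific <- tissue_specific_dmrs(lev, margin = th$hypo_margin)
    # loss/gain events for tissue-specific DMRs, per tissue
    ev <- list()
    for (tis in unique(groups$tissue)) {
      cols <- groups[tissue == tis][order(stage_index), id]
      spec <- which(vapply(run$tissue_specific$hypo, function(h)
        any(groups$tissue[h] == tis), logical(1)))
      for (i in spec) {
        e <- count_mcg_events(lev[i, cols], delta = th$event_delta)
        if (nrow(e)) ev[[length(ev) + 1]] <- data.table(
          tissue = tis, dmr = i, e)
      }
    }
    run$events <- if (length(ev)) rbindlist(ev) else
      data.table(tissue = character(), dmr = integer(),
                 interval = integer(), loss = logical(), gain = logical())
    ann <- run$genome$annotations
    run$categories <- if (nrow(run$dmrs)) suppressWarnings(
      categorize_dmrs(run$dmrs, ann$promoters, ann$cgi, ann$cgi_shores,
                      ann$transposons, enhancer_scores = NULL,
                      effects = run$tissue_specific$effect,
                      score_cutoff = th$enhancer_cutoff)) else factor()
    expressed <- filter_expressed_genes(run$expression$tpm)
    tss <- run$genome$annotations$tss
    tss_expr <- data.table(chrom = tss$chrom, pos = tss$end, gene = tss$gene)[
      gene %in% expressed]
    run$dmr_genes <- if (nrow(run$dmrs))
      link_regions_to_genes(run$dmrs[, .(chrom, start, end)], tss_expr) else
      NULL
  }

  ## ------------------------------------------------------------------ ##
  if ("domains" %in% stages) {
    need("domains", "cg_tracks")
    if (is.null(run$tissue_specific))
      stop("stage 'domains' requires the 'dmr' stage first")
    say("domains: large hypo + DMV + PMD + mCH")
    design <- run$design
    groups <- run$dmr_samples
    # large hypo blocks per tissue
    lh <- list()
    for (tis in unique(groups$tissue)) {
      spec <- which(vapply(run$tissue_specific$hypo, function(h)
        length(h) > 0 && any(groups$tissue[h] == tis), logical(1)))
      lh[[tis]] <- call_large_hypo(run$dmrs[spec])
    }
    run$large_hypo <- lh
    # DMVs: per (tissue, stage) across replicates, then merged
    pairs <- design[, .(ids = list(sample_id)), by = .(tissue, stage)]
    dmv_by_sample <- list()
    for (i in seq_len(nrow(pairs))) {
      ids <- pairs$ids[[i]]
      dmv_by_sample[[paste(pairs$tissue[i], pairs$stage[i], sep = "_")]] <-
        call_dmvs(run$cg_tracks[ids], threshold = th$dmv_threshold,
                  min_bins = th$dmv_min_bins)
    }
    run$dmvs_by_sample <- dmv_by_sample
    run$dmvs <- merge_domains(dmv_by_sample)
    # PMDs in the PMD-prone tissue (liver-like), trained on truth labels
    pt <- unique(run$truth$pmds$tissue)
    ann <- run$genome$annotations
    excl <- rbind(ann$cgi[, .(chrom, start, end)],
                  run$dmvs[, .(chrom, start, end)],
                  ann$hox_like[, .(chrom, start, end)])
    liver <- design[tissue %in% pt]
    feats <- list()
    for (id in liver$sample_id)
      feats[[id]] <- pmd_features(run$cg_sites[[id]],
                                  run$genome$chrom_lengths, exclude = excl,
                                  bin_size = th$pmd_bin,
                                  cov_min = th$pmd_cov_min,
                                  min_sites = th$pmd_min_sites)
    # training sample: the second stage (E13.5-like), replicates combined
    tr_stage <- unique(liver$stage[liver$stage_index == 2])
    tr_ids <- liver[stage == tr_stage, sample_id]
    tr_comb <- copy(run$cg_sites[[tr_ids[1]]])
    if (length(tr_ids) > 1) {
      s2 <- run$cg_sites[[tr_ids[2]]]
      tr_comb[, `:=`(mc = mc + s2$mc, cov = cov + s2$cov)]
    }
    trf <- pmd_features(tr_comb, run$genome$chrom_lengths, exclude = excl,
                        bin_size = th$pmd_bin, cov_min = th$pmd_cov_min,
                        min_sites = th$pmd_min_sites)
    frac_in <- bed_overlap_bases(trf$bins, run$truth$pmds) /
      (trf$bins$end - trf$bins$start)
    labels <- frac_in >= 0.5
    pmd_calls <- list()
    for (st in unique(liver$stage)) {
      ids <- liver[stage == st, sample_id]
      res <- call_pmds(trf$features, labels, lapply(feats[ids], identity),
                       min_len = th$pmd_min_len, gaps = ann$gaps,
                       hox = ann$hox_like, ntree = th$pmd_ntree,
                       seed = config$seed + 31)
      pmd_calls[[paste(pt, st, sep = "_")]] <- res$pmds
    }
    run$pmds_by_stage <- pmd_calls
    run$pmds <- merge_domains(pmd_calls)
    # mCH domains
    run$mch <- call_mch_domains(run$ch_tracks, design,
                                elevation = th$mch_elevation,
                                pseudo = th$mch_pseudo,
                                min_len = th$mch_min_len,
                                min_bins = th$mch_min_bins)
    say("domains: ", nrow(run$mch$domains), " mCH domains after ",
        run$mch$iterations, " exclusion iterations")
    if (nrow(run$mch$domains) >= 3) {   # k-means needs k < n domains
      late <- design[is_control == FALSE & stage_index == max(stage_index),
                     sample_id]
      prof <- mch_domain_profiles(run$mch$domains, run$ch_tracks, late,
                                  pseudo = th$mch_pseudo)
      run$mch_profiles <- prof
      run$mch_clusters <- cluster_mch_domains(
        prof, k = min(2, nrow(prof)), seed = config$seed + 37)
    }
    gb <- run$genome$annotations$gene_bodies
    dom_genes <- gb$gene[bed_overlaps_any(gb, run$mch$domains)]
    expr <- run$expression
    run$mch_domain_genes <- intersect(dom_genes,
                                      filter_expressed_genes(expr$tpm))
    if (length(run$mch_domain_genes))
      run$repression <- mch_repression_zscores(expr$tpm, expr$meta,
                                               run$mch_domain_genes)
  }

  ## ------------------------------------------------------------------ ##
  if ("enrich" %in% stages) {
    if (is.null(run$categories))
      stop("stage 'enrich' requires the 'dmr' stage first")
    say("enrich: hypergeometric + Monte-Carlo tests")
    groups <- run$dmr_samples
    occ <- simulate_motif_occurrences(run$genome, run$truth,
                                      config$seed + 41)
    fb_tissue <- unique(run$truth$dmrs$hypo_tissue)[1]
    spec_tissue <- vapply(seq_len(nrow(run$dmrs)), function(i) {
      h <- run$tissue_specific$hypo[[i]]
      if (!length(h)) NA_character_ else
        names(sort(table(groups$tissue[h]), decreasing = TRUE))[1]
    }, character(1))
    fg <- run$dmrs[!is.na(spec_tissue) & spec_tissue == fb_tissue,
                   .(chrom, start, end)]
    bg <- run$dmrs[!is.na(spec_tissue) & spec_tissue != fb_tissue,
                   .(chrom, start, end)]
    run$motif_enrichment <- if (nrow(fg) && nrow(bg))
      hypergeom_enrichment(fg, bg, occ, extend_to = th$extend_width) else NULL
    # transposon-overlap shuffle test on unxDMRs; when every distal DMR
    # was assigned a regulatory tier, fall back to all distal CG-DMRs so
    # the same machinery is still exercised
    unx <- run$dmrs[as.character(run$categories) %in%
                      c("te-unxDMR", "nte-unxDMR"), .(chrom, start, end)]
    distal <- run$dmrs[!as.character(run$categories) %in%
                         c("CGI-promoter", "non-CGI-promoter", "CGI",
                           "CGI-shore"), .(chrom, start, end)]
    te_regions <- if (nrow(unx)) unx else distal
    run$te_overlap_regions <- if (nrow(unx)) "unxDMRs" else "distal CG-DMRs"
    run$te_overlap <- if (nrow(te_regions))
      mc_overlap_test(te_regions, run$genome$annotations$transposons,
                      run$genome$chrom_lengths,
                      gaps = run$genome$annotations$gaps,
                      k = th$k_permutations, seed = config$seed + 43) else NULL
    genes <- run$genome$annotations$gene_bodies$gene
    tf_like <- genes[seq_along(genes) %% 5 == 0]   # fixed synthetic TF list
    if (!is.null(run$mch_domain_genes) && length(run$mch_domain_genes))
      run$tf_geneset <- mc_geneset_test(run$mch_domain_genes, genes, tf_like,
                                        k = th$k_permutations,
                                        seed = config$seed + 47)
  }

  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' Score a pipeline run against its planted truth
#'
#' @param run result of [run_pipeline()] (through the `domains` stage)
#' @return list of recovery metrics: exact hypo-set recovery fraction over
#'   planted DMRs, DMV/PMD base-level Jaccard, mCH domain recall and
#'   precision, bases of mCH calls inside artefact regions
#' @export
score_recovery <- function(run) {
  truth <- run$truth
  groups <- run$dmr_samples
  margin <- run$config$thresholds$hypo_margin
  # truth hypo-sample sets via the same baseline rule on true levels
  n_dmr <- nrow(truth$dmrs)
  recovered <- logical(n_dmr)
  effects_true <- numeric(n_dmr)
  for (i in seq_len(n_dmr)) {
    centre <- floor((truth$dmrs$start[i] + truth$dmrs$end[i]) / 2)
    tl <- vapply(seq_len(nrow(groups)), function(j)
      true_mcg_level(truth, truth$dmrs$chrom[i], centre,
                     groups$tissue[j], groups$stage_index[j]), numeric(1))
    bl <- baseline_bulk(tl, margin = margin)
    effects_true[i] <- effect_size(tl, bl)
    ov <- bed_overlap_bases(truth$dmrs[i, .(chrom, start, end)], run$dmrs)
    if (ov == 0) next
    cand <- which(bed_overlaps_any(run$dmrs,
                                   truth$dmrs[i, .(chrom, start, end)]))
    ovb <- bed_overlap_bases(run$dmrs[cand],
                             truth$dmrs[i, .(chrom, start, end)])
    best <- cand[which.max(ovb)]
    recovered[i] <- setequal(run$tissue_specific$hypo[[best]], bl$hypo)
  }
  art_overlap <- if (nrow(run$mch$domains))
    sum(bed_overlap_bases(run$mch$domains, truth$artefacts)) else 0
  mch_rp <- domain_recovery(run$mch$domains, truth_bed(truth, "mch_domains"))
  list(
    dmr_hypo_recovery = mean(recovered[effects_true >= truth$min_effect]),
    dmr_recovered = recovered, dmr_true_effects = effects_true,
    dmv_jaccard = jaccard_bases(run$dmvs, truth_bed(truth, "dmvs")),
    pmd_jaccard = jaccard_bases(run$pmds, truth_bed(truth, "pmds")),
    mch_recall = mch_rp$recall,
    mch_precision = mch_rp$precision,
    mch_artefact_bases = art_overlap)
}

#' Write a run's outputs and manifest to a directory
#'
#' @param run a pipeline run
#' @param outdir output directory (created if needed)
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(x, name, writer = write_tsv_file) {
    path <- file.path(outdir, name)
    writer(x, path)
    files <<- c(files, path)
  }
  write_tsv_file <- function(x, path)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$qc)) put(run$qc, "qc.tsv")
  if (!is.null(run$dmrs)) {
    d <- copy(run$dmrs)
    d[, hypo := vapply(hypo, paste, character(1), collapse = ",")]
    put(cbind(d, category = as.character(run$categories),
              baseline = run$tissue_specific$baseline,
              effect = run$tissue_specific$effect), "dmrs.tsv")
    put(as.data.table(run$dmr_levels), "dmr_levels.tsv")
  }
  if (!is.null(run$events)) put(run$events, "events.tsv")
  if (!is.null(run$large_hypo))
    put(rbindlist(run$large_hypo, idcol = "tissue"), "large_hypo.tsv")
  if (!is.null(run$dmvs)) put(run$dmvs, "dmvs.bed", write_bed)
  if (!is.null(run$pmds)) put(run$pmds, "pmds.bed", write_bed)
  if (!is.null(run$mch)) {
    put(run$mch$domains, "mch_domains.bed", write_bed)
    put(run$mch$excluded, "mch_excluded.bed", write_bed)
  }
  if (!is.null(run$repression)) put(run$repression, "repression_z.tsv")
  if (!is.null(run$motif_enrichment))
    put(run$motif_enrichment, "motif_enrichment.tsv")
  if (!is.null(run$te_overlap))
    put(data.table(observed = run$te_overlap$observed,
                   fold = run$te_overlap$fold, p = run$te_overlap$p),
        "te_overlap.tsv")
  manifest <- list(
    seed = run$config$seed,
    stages = names(run),
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(files)
}
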