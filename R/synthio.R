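# Synthetic multi-tissue, multi-stage methylome generator.
#
# The generator emulates the statistical structure of a developmental WGBS
# study: a small genome with annotated CpG and CH sites, a sample design of
# tissues x stages x replicates, planted tissue-specific CG-DMRs following
# prenatal-demethylation (and optional postnatal-remethylation)
# trajectories, constitutively unmethylated DMVs, liver-like PMDs at
# intermediate methylation, mCH domains that accumulate with developmental
# stage, mapping-artefact regions with spurious mCH in every sample, and an
# unmethylated lambda spike-in per sample. Every planted feature and the
# exact true methylation function of every (site, sample) pair is recorded
# in a TruthManifest so downstream callers can be scored against truth.

#' Generate a synthetic genome with annotated cytosine sites
#'
#' CpG dyads are placed at even positions so the two strand positions
#' (p, p+1) never collide with each other or with CH sites. Annotation
#' tracks mirror the usual genomic features: gene TSSs and bodies,
#' promoters (TSS +/- 2.5 kb), CpG islands and their +/- 2 kb shores,
#' transposons, Hox-like exclusion loci and one assembly gap.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param cg_density expected CpG dyads per bp (default 0.01, one per 100 bp)
#' @param ch_density expected CH sites per bp
#' @param n_genes,n_transposons counts of annotation features (whole genome)
#' @param gap_length length of the single assembly gap (0 for none)
#' @param n_hox_like number of Hox-like exclusion loci
#' @param seed RNG seed; output is deterministic given the seed
#' @return object of class `GenomeSpec`
#' @export
generate_genome <- function(chrom_lengths = c(chr1 = 3e6, chr2 = 2e6),
                            cg_density = 0.01, ch_density = 0.12,
                            n_genes = 40, n_transposons = 400,
                            gap_length = 50000, n_hox_like = 2,
                            seed = 1) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (cg_density < 0 || ch_density < 0) stop("densities must be >= 0")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  set.seed(seed)
  chroms <- names(chrom_lengths)

  cg_list <- list(); ch_list <- list()
  ch_contexts <- c("CAC", "CAG", "CAA", "CAT", "CTG", "CTA", "CCA", "CTT")
  ch_weights <- c(0.30, 0.25, 0.08, 0.07, 0.10, 0.06, 0.08, 0.06)
  for (cn in chroms) {
    len <- chrom_lengths[[cn]]
    n_cg <- round(len * cg_density)
    cand <- seq(2L, max(2L, as.integer(len) - 2L), by = 2L)
    if (n_cg > length(cand)) stop("cg_density too high for chromosome ", cn)
    cg_pos <- if (n_cg > 0) sort(sample(cand, n_cg)) else integer(0)
    cg_list[[cn]] <- data.table(
      chrom = cn, pos = cg_pos,
      context = if (n_cg) paste0("CG", sample(c("A", "C", "G", "T"), n_cg,
                                              replace = TRUE)) else character(0))
    n_ch <- round(len * ch_density)
    occupied <- logical(len)
    occupied[cg_pos] <- TRUE
    occupied[pmin(cg_pos + 1L, len)] <- TRUE
    free <- which(!occupied)
    if (n_ch > length(free)) stop("ch_density too high for chromosome ", cn)
    ch_pos <- if (n_ch > 0) sort(sample(free, n_ch)) else integer(0)
    ch_list[[cn]] <- data.table(
      chrom = cn, pos = ch_pos,
      strand = if (n_ch) sample(c("+", "-"), n_ch, replace = TRUE) else character(0),
      context = if (n_ch) sample(ch_contexts, n_ch, replace = TRUE,
                                 prob = ch_weights) else character(0))
  }
  cg <- rbindlist(cg_list); ch <- rbindlist(ch_list)

  # annotations ----------------------------------------------------------
  genes_per_chrom <- pmax(1L, round(n_genes * chrom_lengths / sum(chrom_lengths)))
  tss_list <- list()
  for (i in seq_along(chroms)) {
    len <- chrom_lengths[[i]]
    cand <- seq(20000, max(30000, len - 40000), by = 1000)
    n <- min(genes_per_chrom[[i]], length(cand))
    tss_list[[i]] <- data.table(chrom = chroms[i], pos = sort(sample(cand, n)))
  }
  tss <- rbindlist(tss_list)
  tss[, gene := sprintf("gene%03d", .I)]
  lens <- function(cn) chrom_lengths[[cn]]
  clip <- function(x) {
    x[, start := pmax(0, start)]
    x[, end := pmin(end, chrom_lengths[chrom])]
    x[start < end]
  }
  gene_bodies <- clip(data.table(chrom = tss$chrom, start = tss$pos - 1,
                                 end = tss$pos - 1 + 20000, gene = tss$gene))
  promoters <- clip(data.table(chrom = tss$chrom, start = tss$pos - 1 - 2500,
                               end = tss$pos + 2500, gene = tss$gene))
  cgi_idx <- seq(1, nrow(tss), by = 2)                      # half the promoters
  cgi <- clip(data.table(chrom = tss$chrom[cgi_idx],
                         start = tss$pos[cgi_idx] - 751,
                         end = tss$pos[cgi_idx] + 750))
  # a few distal CGIs
  n_distal_cgi <- 5
  dc <- sample(chroms, n_distal_cgi, replace = TRUE, prob = chrom_lengths)
  ds <- vapply(dc, function(cn) sample.int(lens(cn) - 3000, 1), numeric(1))
  cgi <- rbind(cgi, clip(data.table(chrom = dc, start = ds, end = ds + 1500)))
  cgi <- bed_reduce(cgi)
  shores <- bed_setdiff(
    clip(data.table(chrom = rep(cgi$chrom, 2),
                    start = c(cgi$start - 2000, cgi$end),
                    end = c(cgi$start, cgi$end + 2000))),
    cgi)
  tc <- sample(chroms, n_transposons, replace = TRUE, prob = chrom_lengths)
  tw <- sample(150:600, n_transposons, replace = TRUE)
  ts <- vapply(seq_len(n_transposons),
               function(i) sample.int(lens(tc[i]) - tw[i], 1), numeric(1))
  transposons <- data.table(chrom = tc, start = ts, end = ts + tw,
                            name = sprintf("TE%04d", seq_len(n_transposons)))
  setorder(transposons, chrom, start)
  hc <- sample(chroms, n_hox_like, replace = TRUE, prob = chrom_lengths)
  hs <- vapply(hc, function(cn) sample.int(lens(cn) - 20000, 1), numeric(1))
  hox_like <- clip(data.table(chrom = hc, start = hs, end = hs + 20000))
  gaps <- if (gap_length > 0) {
    gc <- chroms[length(chroms)]
    gs <- round(lens(gc) * 0.4)
    data.table(chrom = gc, start = gs,
               end = min(gs + gap_length, lens(gc)))
  } else empty_bed()

  genome <- structure(list(
    chrom_names = chroms,
    chrom_lengths = chrom_lengths,
    cg = cg, ch = ch,
    annotations = list(
      tss = data.table(chrom = tss$chrom, start = tss$pos - 1, end = tss$pos,
                       gene = tss$gene),
      gene_bodies = gene_bodies, promoters = promoters,
      cgi = cgi, cgi_shores = shores, transposons = transposons,
      hox_like = hox_like, gaps = gaps),
    cg_density = cg_density, ch_density = ch_density, seed = seed),
    class = "GenomeSpec")
  validate_genome(genome)
  genome
}

validate_genome <- function(g) {
  stopifnot(inherits(g, "GenomeSpec"))
  for (cn in g$chrom_names) {
    cgp <- g$cg[chrom == cn, pos]; chp <- g$ch[chrom == cn, pos]
    if (is.unsorted(cgp, strictly = TRUE)) stop("CG positions not strictly increasing")
    if (is.unsorted(chp, strictly = TRUE)) stop("CH positions not strictly increasing")
    if (length(cgp) && max(cgp) + 1 > g$chrom_lengths[[cn]]) stop("CG position out of bounds")
    if (length(chp) && max(chp) > g$chrom_lengths[[cn]]) stop("CH position out of bounds")
    if (length(intersect(c(cgp, cgp + 1L), chp)) > 0)
      stop("CG and CH position sets overlap")
  }
  for (tr in g$annotations) {
    if (nrow(tr) && any(tr$end > g$chrom_lengths[tr$chrom]))
      stop("annotation interval out of chromosome bounds")
  }
  invisible(g)
}

#' Build a sample design table
#'
#' One row per (tissue, stage, replicate). Control samples are those
#' expected to carry no genuine mCH (early embryonic stages, excluding
#' heart-like tissues); their true mCH is zero everywhere except in planted
#' artefact regions, which emulate mapping artefacts shared by all samples.
#'
#' @param tissues,stages character vectors; `stages` in chronological order
#' @param replicates replicates per (tissue, stage)
#' @param coverage_mean mean read depth per cytosine strand position
#' @param nonconversion_rate bisulfite non-conversion probability (< 0.05)
#' @param control_stages stages whose samples are mCH-free controls
#' @param control_exclude_tissues tissues never used as controls
#' @return `data.table` with one row per sample
#' @export
make_design <- function(tissues = c("forebrain", "heart", "liver"),
                        stages = c("E10.5", "E13.5", "E16.5", "P0"),
                        replicates = 2,
                        coverage_mean = 30,
                        nonconversion_rate = 0.005,
                        control_stages = stages[1],
                        control_exclude_tissues = "heart") {
  if (coverage_mean <= 0) stop("coverage_mean must be > 0")
  if (nonconversion_rate < 0 || nonconversion_rate >= 0.05)
    stop("nonconversion_rate must be in [0, 0.05)")
  d <- CJ(tissue = tissues, stage = factor(stages, levels = stages),
          replicate = seq_len(replicates), sorted = FALSE)
  setorder(d, tissue, stage, replicate)
  d[, stage := as.character(stage)]
  d[, stage_index := match(stage, stages)]
  d[, is_control := stage %in% control_stages &
        !tissue %in% control_exclude_tissues]
  d[, coverage_mean := coverage_mean]
  d[, nonconversion_rate := nonconversion_rate]
  d[, sample_id := sprintf("%s_%s_r%d", tissue, stage, replicate)]
  if (anyDuplicated(d$sample_id)) stop("(tissue, stage, replicate) not unique")
  setcolorder(d, c("sample_id", "tissue", "stage", "stage_index",
                   "replicate", "is_control"))
  d[]
}

# place n non-overlapping intervals, avoiding `occupied` with a margin
place_intervals <- function(chrom_lengths, widths, occupied, margin = 10000,
                            align = 1, max_tries = 2000, accept = NULL) {
  out <- empty_bed()
  chroms <- names(chrom_lengths)
  for (w in widths) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cn <- sample(chroms, 1, prob = chrom_lengths)
      hi <- chrom_lengths[[cn]] - w - margin
      if (hi <= margin) next
      s <- sample.int(hi - margin, 1) + margin
      if (align > 1) s <- (s %/% align) * align
      cand <- data.table(chrom = cn, start = s, end = s + w)
      grown <- data.table(chrom = cn, start = max(0, s - margin), end = s + w + margin)
      if (nrow(occupied) && any(bed_overlaps_any(grown, occupied))) next
      if (!is.null(accept) && !accept(cand)) next
      out <- rbind(out, cand)
      occupied <- rbind(occupied,
                        cand[, .(chrom, start, end)])
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place a feature of width ", w,
                      "; requested features exceed usable genome space")
  }
  list(features = out, occupied = occupied)
}

#' Plant ground-truth methylome features
#'
#' Plants tissue-specific CG-DMRs with per-stage trajectory functions,
#' DMVs, PMDs, mCH domains and artefact regions, all mutually disjoint and
#' clear of assembly gaps. DMR trajectories are piecewise linear in stage
#' order: shape `"loss"` descends from the background to `dmr_low`; shape
#' `"loss_regain"` reaches `dmr_low` before the final stage and then
#' regains methylation (postnatal remethylation).
#'
#' @param genome a `GenomeSpec`
#' @param design sample design from [make_design()]
#' @param config named list overriding any default (see source)
#' @return object of class `TruthManifest`
#' @export
plant_truth <- function(genome, design, config = list()) {
  stages <- unique(design$stage[order(design$stage_index)])
  n_stages <- length(stages)
  tissues <- unique(design$tissue)
  if (length(tissues) < 2 || n_stages < 2)
    stop("need >= 2 tissues and >= 2 stages to plant DMR trajectories")

  cfg <- utils::modifyList(list(
    background_mcg = 0.85,
    site_sd = 0.08, site_range = c(0.6, 0.98), cgi_level = 0.05,
    n_dmr_clusters_per_tissue = 1, dmr_cluster_size = 3,
    dmr_cluster_width = 800, dmr_cluster_gap = 600,
    background_mch = c(0.002, 0.005, 0.010, 0.015)[seq_len(n_stages)],
    n_dmrs_per_tissue = 10,
    dmr_widths = c(600, 1500),
    dmr_low = 0.15,
    min_effect = 0.4,
    regain_fraction = 0.3,
    dmr_tissues = setdiff(tissues, "liver"),
    n_dmvs = 6, dmv_widths = c(5000, 10000), dmv_level = 0.05,
    pmd_tissue = if ("liver" %in% tissues) "liver" else tissues[length(tissues)],
    n_pmds = 2, pmd_widths = c(3e5, 5e5), pmd_level = 0.5,
    n_mch_domains = 5, mch_widths = c(25000, 50000), mch_elevation = 2,
    n_artefacts = 3, artefact_widths = c(20000, 30000), artefact_mch = 0.04,
    seed = 99
  ), config)
  if (length(cfg$background_mch) != n_stages)
    stop("background_mch must have one value per stage")
  if (cfg$mch_elevation < 1.5) stop("mCH elevation factor must be >= 1.5")
  set.seed(cfg$seed)

  occupied <- rbind(genome$annotations$gaps[, .(chrom, start, end)],
                    genome$annotations$hox_like[, .(chrom, start, end)])

  rwid <- function(n, r, align = 1)
    if (n > 0) pmax(align, round(runif(n, r[1], r[2]) / align) * align) else numeric(0)

  # large features are placed first so contiguous space is still available
  pl <- place_intervals(genome$chrom_lengths,
                        rep_len(cfg$pmd_widths, cfg$n_pmds),
                        occupied, margin = 20000, align = 10000)
  pmds <- pl$features; occupied <- pl$occupied
  pmds[, `:=`(tissue = rep(cfg$pmd_tissue, .N), level = rep(cfg$pmd_level, .N))]

  pl <- place_intervals(genome$chrom_lengths,
                        rwid(cfg$n_mch_domains, cfg$mch_widths, 5000),
                        occupied, margin = 25000, align = 5000)
  mch_domains <- pl$features; occupied <- pl$occupied
  mch_domains[, elevation := rep(cfg$mch_elevation, .N)]

  pl <- place_intervals(genome$chrom_lengths,
                        rwid(cfg$n_artefacts, cfg$artefact_widths, 5000),
                        occupied, margin = 25000, align = 5000)
  artefacts <- pl$features; occupied <- pl$occupied
  artefacts[, level := rep(cfg$artefact_mch, .N)]

  pl <- place_intervals(genome$chrom_lengths,
                        rwid(cfg$n_dmvs, cfg$dmv_widths, 1000),
                        occupied, margin = 5000, align = 1000)
  dmvs <- pl$features; occupied <- pl$occupied
  dmvs[, level := rep(cfg$dmv_level, .N)]

  # DMRs only make sense where CpGs are locally adequate: require enough
  # dyads, spaced so that a >= 3-DMS block is attainable at a 250-bp merge
  # distance
  dmr_ok <- function(cand) {
    p <- genome$cg[chrom == cand$chrom &
                     pos > cand$start & pos <= cand$end, pos]
    length(p) >= 5 && max(diff(p)) <= 200
  }
  pl <- place_intervals(genome$chrom_lengths,
                        rwid(cfg$n_dmrs_per_tissue * length(cfg$dmr_tissues),
                             cfg$dmr_widths),
                        occupied, margin = 5000, accept = dmr_ok)
  dmrs <- pl$features; occupied <- pl$occupied
  if (nrow(dmrs)) {
    dmrs[, hypo_tissue := rep(cfg$dmr_tissues, length.out = .N)]
    n_regain <- round(cfg$regain_fraction * nrow(dmrs))
    dmrs[, shape := c(rep("loss_regain", n_regain),
                      rep("loss", .N - n_regain))[sample.int(.N)]]
  } else {
    dmrs[, `:=`(hypo_tissue = character(0), shape = character(0))]
  }
  # clustered DMRs: groups of nearby same-tissue DMRs whose merged span
  # exceeds the large-hypo minimum, so block callers have real targets
  if (cfg$n_dmr_clusters_per_tissue > 0) {
    cs <- cfg$dmr_cluster_size
    cw <- cfg$dmr_cluster_width
    cg_gap <- cfg$dmr_cluster_gap
    parent_w <- cs * cw + (cs - 1) * cg_gap
    member_starts <- (seq_len(cs) - 1) * (cw + cg_gap)
    cluster_ok <- function(cand) {
      all(vapply(member_starts, function(off) {
        p <- genome$cg[chrom == cand$chrom &
                         pos > cand$start + off &
                         pos <= cand$start + off + cw, pos]
        length(p) >= 5 && max(diff(p)) <= 250
      }, logical(1)))
    }
    for (tis in cfg$dmr_tissues) {
      for (ci in seq_len(cfg$n_dmr_clusters_per_tissue)) {
        pl <- place_intervals(genome$chrom_lengths, parent_w, occupied,
                              margin = 5000, accept = cluster_ok)
        occupied <- pl$occupied
        p <- pl$features
        members <- data.table(
          chrom = p$chrom,
          start = p$start + (seq_len(cs) - 1) * (cw + cg_gap),
          end = p$start + (seq_len(cs) - 1) * (cw + cg_gap) + cw,
          hypo_tissue = tis, shape = "loss")
        dmrs <- rbind(dmrs, members)
      }
    }
  }
  traj <- matrix(cfg$background_mcg, nrow = nrow(dmrs), ncol = n_stages)
  for (i in seq_len(nrow(dmrs))) {
    tr <- seq(cfg$background_mcg, cfg$dmr_low, length.out = n_stages)
    if (dmrs$shape[i] == "loss_regain") {
      # lose mCG prenatally, regain strongly after birth (final stage)
      tr[n_stages] <- min(tr[n_stages - 1] + 0.5, cfg$background_mcg)
    }
    traj[i, ] <- tr
  }
  if (nrow(dmrs) && any(cfg$background_mcg - apply(traj, 1, min) < cfg$min_effect))
    stop("planted DMR effect below configured minimum")

  # per-CpG-site background: CGI sites are unmethylated, the rest jitter
  # around the global background (shared across samples; planted features
  # override these exactly)
  sb <- genome$cg[, .(chrom, pos)]
  sb[, level := pmin(pmax(rnorm(.N, cfg$background_mcg, cfg$site_sd),
                          cfg$site_range[1]), cfg$site_range[2])]
  in_cgi <- !is.na(point_interval_index(sb$chrom, sb$pos,
                                        genome$annotations$cgi))
  sb[in_cgi, level := cfg$cgi_level]
  setkey(sb, chrom, pos)

  structure(list(
    design = copy(design), stages = stages,
    site_background = sb,
    background_mcg = cfg$background_mcg,
    background_mch = setNames(cfg$background_mch, stages),
    dmrs = dmrs, dmr_trajectories = traj,
    dmvs = dmvs, pmds = pmds, mch_domains = mch_domains,
    artefacts = artefacts,
    min_effect = cfg$min_effect, seed = cfg$seed), class = "TruthManifest")
}

#' True mCG level of positions for one sample
#'
#' @param truth a `TruthManifest`
#' @param chrom,pos vectors of 1-based positions
#' @param tissue,stage_index the sample's tissue and stage
#' @return numeric vector of true mCG levels
#' @export
true_mcg_level <- function(truth, chrom, pos, tissue, stage_index) {
  m <- rep(truth$background_mcg, length(pos))
  if (!is.null(truth$site_background)) {
    q <- data.table(chrom = chrom, pos = pos)
    hit <- truth$site_background[q, on = c("chrom", "pos"), level]
    m[!is.na(hit)] <- hit[!is.na(hit)]
  }
  if (nrow(truth$dmrs)) {
    # inside a planted DMR the level is exact for every tissue: the
    # trajectory in the hypo tissue, the flat background elsewhere
    idx <- point_interval_index(chrom, pos, truth$dmrs)
    inside <- !is.na(idx)
    m[inside] <- truth$background_mcg
    hit <- inside & truth$dmrs$hypo_tissue[ifelse(is.na(idx), 1L, idx)] == tissue
    m[hit] <- truth$dmr_trajectories[cbind(idx[hit], stage_index)]
  }
  if (nrow(truth$pmds)) {
    idx <- point_interval_index(chrom, pos, truth$pmds)
    inside <- !is.na(idx)
    m[inside] <- truth$background_mcg
    hit <- inside & truth$pmds$tissue[ifelse(is.na(idx), 1L, idx)] == tissue
    m[hit] <- truth$pmds$level[idx[hit]]
  }
  idx <- point_interval_index(chrom, pos, truth$dmvs)
  m[!is.na(idx)] <- truth$dmvs$level[idx[!is.na(idx)]]
  m
}

#' True mCH level of positions for one sample
#'
#' Control samples have zero genuine mCH; artefact regions show spurious
#' mCH in every sample, controls included.
#'
#' @inheritParams true_mcg_level
#' @param sample one row of the design (list or single-row data.frame)
#' @export
true_mch_level <- function(truth, chrom, pos, sample) {
  base <- if (isTRUE(sample$is_control)) 0 else
    truth$background_mch[[sample$stage_index]]
  m <- rep(base, length(pos))
  if (nrow(truth$mch_domains)) {
    idx <- point_interval_index(chrom, pos, truth$mch_domains)
    hit <- !is.na(idx)
    m[hit] <- base * truth$mch_domains$elevation[idx[hit]]
  }
  if (nrow(truth$artefacts)) {
    idx <- point_interval_index(chrom, pos, truth$artefacts)
    hit <- !is.na(idx)
    m[hit] <- truth$artefacts$level[idx[hit]]
  }
  m
}

#' Simulate allc count tables for one sample
#'
#' Per strand position, total read count ~ Poisson(coverage_mean) and
#' methylated count ~ Binomial(total, m + (1 - m) * r) where m is the true
#' level and r the non-conversion rate (failed conversion affects only
#' unmethylated cytosines). CpG dyads are emitted as two strand rows
#' sharing one true level. The lambda spike-in is fully unmethylated, so
#' its observed methylated fraction estimates r.
#'
#' @param genome a `GenomeSpec`
#' @param truth a `TruthManifest`
#' @param sample one row of the design
#' @param seed RNG seed (deterministic output for a fixed seed)
#' @param n_lambda_sites lambda spike-in site count
#' @return list with elements `allc` and `lambda`, both allc tables
#' @export
simulate_counts <- function(genome, truth, sample, seed,
                            n_lambda_sites = 20000) {
  set.seed(seed)
  r <- sample$nonconversion_rate
  cm <- sample$coverage_mean

  cg <- genome$cg
  m_cg <- true_mcg_level(truth, cg$chrom, cg$pos, sample$tissue,
                         sample$stage_index)
  n <- nrow(cg)
  cg_rows <- data.table(
    chrom = rep(cg$chrom, each = 2),
    pos = as.integer(rep(cg$pos, each = 2) + c(0L, 1L)),
    strand = rep(c("+", "-"), n),
    context = rep(cg$context, each = 2),
    m = rep(m_cg, each = 2))

  ch <- genome$ch
  m_ch <- true_mch_level(truth, ch$chrom, ch$pos, sample)
  ch_rows <- data.table(chrom = ch$chrom, pos = ch$pos, strand = ch$strand,
                        context = ch$context, m = m_ch)

  allc <- rbind(cg_rows, ch_rows)
  setorder(allc, chrom, pos)
  allc[, cov := rpois(.N, cm)]
  allc[, mc := rbinom(.N, cov, m + (1 - m) * r)]
  allc[, m := NULL]

  lam <- data.table(chrom = "lambda", pos = seq_len(n_lambda_sites),
                    strand = "+",
                    context = rep_len(c("CGA", "CAA", "CTG", "CCT"),
                                      n_lambda_sites))
  lam[, cov := rpois(.N, cm)]
  lam[, mc := rbinom(.N, cov, r)]
  list(allc = allc[], lambda = lam[])
}

#' Simulate every sample of a design
#'
#' @param genome,truth as in [simulate_counts()]
#' @param seed master seed; per-sample seeds are derived deterministically
#' @param dir if non-NULL, write the dataset layout
#'   `dir/{tissue}_{stage}_r{rep}/allc.tsv` + `lambda.tsv` + `dir/truth.json`
#' @return named list of [simulate_counts()] results (invisibly when
#'   writing to `dir`)
#' @export
simulate_dataset <- function(genome, truth, seed = 1, dir = NULL) {
  design <- truth$design
  out <- vector("list", nrow(design))
  names(out) <- design$sample_id
  for (i in seq_len(nrow(design))) {
    smp <- as.list(design[i])
    out[[i]] <- simulate_counts(genome, truth, smp,
                                seed = (seed * 1009L + i * 101L) %% .Machine$integer.max)
    if (!is.null(dir)) {
      d <- file.path(dir, design$sample_id[i])
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_allc(out[[i]]$allc, file.path(d, "allc.tsv"))
      write_allc(out[[i]]$lambda, file.path(d, "lambda.tsv"))
    }
  }
  if (!is.null(dir)) {
    write_manifest(truth, file.path(dir, "truth.json"))
    invisible(out)
  } else out
}

#' Serialize a TruthManifest to JSON
#' @param truth a `TruthManifest`
#' @param path output path
#' @export
write_manifest <- function(truth, path) {
  x <- unclass(truth)
  x$background_mch <- as.list(x$background_mch)  # keep stage names in JSON
  x$dmr_trajectories <- unname(apply(truth$dmr_trajectories, 1, c,
                                     simplify = FALSE))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a TruthManifest back from JSON
#' @param path JSON written by [write_manifest()]
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("design", "site_background", "dmrs", "dmvs", "pmds",
               "mch_domains", "artefacts"))
    x[[nm]] <- as.data.table(x[[nm]])
  x$dmr_trajectories <- if (is.matrix(x$dmr_trajectories))
    x$dmr_trajectories
  else if (length(x$dmr_trajectories))
    do.call(rbind, x$dmr_trajectories)
  else matrix(numeric(0), 0, length(x$stages))
  x$background_mch <- unlist(x$background_mch)
  if (!is.null(x$site_background)) setkey(x$site_background, chrom, pos)
  structure(x, class = "TruthManifest")
}

#' Planted features of one kind as a BED table
#' @param truth a `TruthManifest`
#' @param kind one of "dmrs", "dmvs", "pmds", "mch_domains", "artefacts"
#' @export
truth_bed <- function(truth, kind = c("dmrs", "dmvs", "pmds", "mch_domains",
                                      "artefacts")) {
  kind <- match.arg(kind)
  truth[[kind]][, .(chrom, start, end)]
}
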