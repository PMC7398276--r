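# Large hypomethylated domains, DMVs, random-forest PMDs, change-point
# mCH domains with iterative artefact exclusion, mCH-domain profiles and
# clustering, and the repression z-score contrast.

#' Large hypomethylated CG-DMR blocks
#'
#' Per tissue, tissue-specific CG-DMRs within `gap` bp of each other are
#' merged; merged blocks shorter than `min_len` are dropped.
#'
#' @param dmrs BED table of one tissue's tissue-specific CG-DMRs
#' @param gap merge distance (default 1000)
#' @param min_len minimum block length (default 2000)
#' @return BED table
#' @export
call_large_hypo <- function(dmrs, gap = 1000, min_len = 2000) {
  out <- bed_reduce(dmrs, gap = gap)
  out[end - start >= min_len]
}

# runs of low-methylation bins in one track; no-data bins are skipped
# (neither break the run nor count toward min_bins), unless more than
# max_gap_bins of them intervene.
dmv_runs <- function(track, threshold = 0.15, min_bins = 5,
                     max_gap_bins = Inf) {
  out <- list()
  for (cn in unique(track$chrom)) {
    tr <- track[chrom == cn][order(start)]
    hypo <- !is.na(tr$level) & tr$level < threshold
    breaker <- !is.na(tr$level) & tr$level >= threshold
    grp <- cumsum(breaker)
    for (g in unique(grp[hypo])) {
      idx <- which(hypo & grp == g)
      if (!length(idx)) next
      splits <- if (is.finite(max_gap_bins) && length(idx) > 1)
        cumsum(c(0, diff(idx) - 1 > max_gap_bins)) else rep(0, length(idx))
      for (sg in unique(splits)) {
        ii <- idx[splits == sg]
        if (length(ii) >= min_bins)
          out[[length(out) + 1]] <- data.table(
            chrom = cn, start = tr$start[min(ii)], end = tr$end[max(ii)],
            n_bins = length(ii))
      }
    }
  }
  if (!length(out)) return(data.table(chrom = character(), start = numeric(),
                                      end = numeric(), n_bins = integer()))
  rbindlist(out)
}

#' Call DNA methylation valleys (DMVs) for one sample
#'
#' Per replicate, runs of 1-kb bins with mCG level below `threshold` are
#' merged into blocks; no-data bins are skipped (they neither break a run
#' nor count toward the minimum). Blocks with at least `min_bins`
#' with-data bins are DMVs. Replicate reconciliation keeps DMVs of either
#' replicate that overlap a DMV of the other and merges overlaps; with a
#' single replicate, reconciliation is skipped with a warning.
#'
#' @param tracks list of 1-kb CG `LevelTrack`s, one per replicate
#' @param threshold mCG cutoff (default 0.15)
#' @param min_bins minimum with-data bins (default 5)
#' @param max_gap_bins maximum run of internal no-data bins (default Inf)
#' @return BED table of this sample's DMVs
#' @export
call_dmvs <- function(tracks, threshold = 0.15, min_bins = 5,
                      max_gap_bins = Inf) {
  runs <- lapply(tracks, dmv_runs, threshold = threshold,
                 min_bins = min_bins, max_gap_bins = max_gap_bins)
  if (length(runs) == 1) {
    warning("single replicate: DMV replicate reconciliation skipped")
    return(bed_reduce(runs[[1]]))
  }
  a <- runs[[1]]; b <- runs[[2]]
  keep_a <- a[bed_overlaps_any(a, b)]
  keep_b <- b[bed_overlaps_any(b, a)]
  bed_reduce(rbind(keep_a[, .(chrom, start, end)],
                   keep_b[, .(chrom, start, end)]))
}

#' Merge domain calls across samples into one list
#' @param domain_list list of BED tables
#' @export
merge_domains <- function(domain_list) {
  bed_reduce(rbindlist(lapply(domain_list, function(x)
    x[, .(chrom, start, end)])))
}

#' Percentile features of 10-kb bins for PMD classification
#'
#' Per bin, the 5th-95th percentiles (steps of 5) of per-site methylation
#' fractions. Sites inside CGIs, DMVs or Hox-like exclusion loci and sites
#' under `cov_min` reads are excluded first; bins with fewer than
#' `min_sites` remaining sites get NA features (no-feature sentinel).
#'
#' @param sites strand-merged CG allc table for one sample
#' @param chrom_lengths named chromosome lengths
#' @param exclude BED table of excluded regions (CGIs, DMVs, Hox loci)
#' @param bin_size bin width (default 10000)
#' @param cov_min minimum per-site coverage (default 5)
#' @param min_sites minimum sites per bin (default 10)
#' @param probs percentile grid (default 5th-95th by 5)
#' @param nonconversion per-site level correction (default 0)
#' @return list: `bins` (BED + n_sites), `features` (bins x 19 matrix)
#' @export
pmd_features <- function(sites, chrom_lengths, exclude = NULL,
                         bin_size = 10000, cov_min = 5, min_sites = 10,
                         probs = seq(0.05, 0.95, by = 0.05),
                         nonconversion = 0) {
  s <- as.data.table(sites)[cov >= cov_min]
  if (!is.null(exclude) && nrow(exclude)) {
    idx <- point_interval_index(s$chrom, s$pos, bed_reduce(exclude))
    s <- s[is.na(idx)]
  }
  s[, level := methylation_level(mc, cov, nonconversion)]
  s[, start := ((pos - 1) %/% bin_size) * bin_size]
  grid <- rbindlist(lapply(names(chrom_lengths), function(cn) {
    starts <- seq(0, chrom_lengths[[cn]] - 1, by = bin_size)
    data.table(chrom = cn, start = starts,
               end = pmin(starts + bin_size, chrom_lengths[[cn]]))
  }))
  agg <- s[, c(list(n_sites = .N),
               as.list(quantile(level, probs = probs, names = FALSE))),
           by = .(chrom, start)]
  out <- merge(grid, agg, by = c("chrom", "start"), all.x = TRUE)
  setorder(out, chrom, start)
  out[is.na(n_sites), n_sites := 0L]
  fcols <- setdiff(names(out), c("chrom", "start", "end", "n_sites"))
  feats <- as.matrix(out[, fcols, with = FALSE])
  colnames(feats) <- paste0("q", probs * 100)
  feats[out$n_sites < min_sites, ] <- NA_real_
  list(bins = out[, .(chrom, start, end, n_sites)], features = feats)
}

#' Call partially methylated domains (PMDs) with a random forest
#'
#' A random-forest classifier is trained on labelled bins (percentile
#' features from [pmd_features()]), then each replicate's bins are
#' classified; consecutive PMD bins are merged, blocks shorter than
#' `min_len` or overlapping assembly gaps are dropped, the replicates are
#' intersected (regions covered by PMD calls in both; a single replicate
#' is used alone), and anything overlapping the Hox-like exclusion loci is
#' removed.
#'
#' @param train_features matrix of training features (rows with NA dropped)
#' @param train_labels logical/factor PMD labels, parallel to rows
#' @param rep_features list per replicate: list(bins = BED, features =
#'   matrix) as returned by [pmd_features()]
#' @param min_len minimum block length (default 1e5)
#' @param gaps,hox BED tables of assembly gaps and exclusion loci
#' @param ntree forest size (default 1000; 10000 for full fidelity)
#' @param seed RNG seed
#' @return list: `pmds` (BED), `per_replicate` (list of BEDs), `model`
#' @export
call_pmds <- function(train_features, train_labels, rep_features,
                      min_len = 1e5, gaps = NULL, hox = NULL,
                      ntree = 1000, seed = 1) {
  ok <- complete.cases(train_features)
  y <- factor(ifelse(as.logical(train_labels)[ok], "PMD", "nonPMD"),
              levels = c("nonPMD", "PMD"))
  set.seed(seed)
  model <- randomForest::randomForest(x = train_features[ok, , drop = FALSE],
                                      y = y, ntree = ntree)
  per_rep <- lapply(rep_features, function(rf) {
    feats <- rf$features
    okb <- complete.cases(feats)
    pred <- rep(FALSE, nrow(feats))
    if (any(okb))
      pred[okb] <- predict(model, feats[okb, , drop = FALSE]) == "PMD"
    blocks <- bed_reduce(rf$bins[pred])
    blocks <- blocks[end - start >= min_len]
    if (!is.null(gaps) && nrow(gaps))
      blocks <- blocks[!bed_overlaps_any(blocks, gaps)]
    blocks
  })
  pmds <- if (length(per_rep) == 1) per_rep[[1]] else {
    both <- Reduce(bed_intersect, per_rep)
    both[end - start >= min_len]
  }
  if (!is.null(hox) && nrow(hox) && nrow(pmds))
    pmds <- pmds[!bed_overlaps_any(pmds, hox)]
  list(pmds = pmds, per_replicate = per_rep, model = model)
}

# segment one 5-kb track into chunks, ignoring no-data bins and bins
# overlapping `excluded`; chunk level = unweighted mean of its usable bins
segment_chunks <- function(track, excluded = NULL, penalty = NULL,
                           scale = 1000, minseglen = 2) {
  out <- list()
  usable <- !is.na(track$level)
  if (!is.null(excluded) && nrow(excluded))
    usable <- usable & !bed_overlaps_any(track[, .(chrom, start, end)],
                                         excluded)
  for (cn in unique(track$chrom)) {
    sel <- track$chrom == cn & usable
    tr <- track[sel]
    if (!nrow(tr)) next
    x <- tr$level * scale
    # scaled mCH levels make unit variance a sensible noise floor; without
    # it, near-zero control samples over-segment and artefact interiors
    # evade the elevation rule
    pen <- if (is.null(penalty)) default_penalty(x, min_var = 1) else penalty
    seg <- pelt_segment(x, penalty = pen, minseglen = minseglen)
    segs <- seg$segments
    out[[cn]] <- data.table(
      chrom = cn,
      start = tr$start[segs$first],
      end = tr$end[segs$last],
      level = segs$mean / scale,
      n_bins = segs$last - segs$first + 1L)
  }
  if (!length(out)) return(data.table(chrom = character(), start = numeric(),
                                      end = numeric(), level = numeric(),
                                      n_bins = integer()))
  rbindlist(out)
}

#' Elevated chunks among segmented neighbours
#'
#' A chunk is a candidate mCH domain when its level is at least
#' `elevation` times the level of both its upstream and downstream
#' neighbouring chunks (a pseudo-level avoids division by zero); terminal
#' chunks have only one neighbour and are never called.
#'
#' @param chunks output of `segment_chunks` for one sample
#' @param elevation fold threshold (default 1.5)
#' @param pseudo pseudo-mCH level (default 0.001)
#' @return BED table of elevated chunks
#' @export
elevated_chunks <- function(chunks, elevation = 1.5, pseudo = 0.001) {
  out <- list()
  for (cn in unique(chunks$chrom)) {
    ch <- chunks[chrom == cn][order(start)]
    n <- nrow(ch)
    if (n < 3) next
    i <- 2:(n - 1)
    up <- ch$level[i - 1]; dn <- ch$level[i + 1]; lev <- ch$level[i]
    hit <- lev / (up + pseudo) >= elevation & lev / (dn + pseudo) >= elevation
    if (any(hit)) out[[cn]] <- ch[i[hit]]
  }
  if (!length(out)) return(data.table(chrom = character(), start = numeric(),
                                      end = numeric(), level = numeric(),
                                      n_bins = integer()))
  rbindlist(out)
}

#' Call mCH domains by iterative change-point segmentation
#'
#' Stage 1 iterates over the control samples (assumed mCH-free): each is
#' segmented, chunks at least `elevation` times both neighbours are
#' artefact candidates and join the exclusion list; bins overlapping
#' excluded regions are ignored in later passes; iteration stops when the
#' exclusion list stops growing (it only ever grows, so the loop
#' terminates; `max_iter` guards against pathological inputs). Stage 2
#' applies the same segmentation + elevation rule to all samples; per
#' (tissue, stage) only regions found in both replicates are kept, regions
#' shorter than `min_len` or spanning fewer than `min_bins` bins are
#' dropped, and the per-tissue calls are merged into one final list.
#'
#' @param tracks named list of 5-kb CH `LevelTrack`s, one per sample
#' @param meta `data.table` with sample_id, tissue, stage, replicate,
#'   is_control matching `names(tracks)`
#' @param elevation fold-change threshold over both neighbours (1.5)
#' @param pseudo pseudo-mCH level (0.001)
#' @param penalty segmentation penalty (NULL = [default_penalty()] per
#'   series)
#' @param scale level scaling before segmentation (1000)
#' @param min_len,min_bins minimum domain length (15 kb) and bin span (3)
#' @param max_iter exclusion-loop iteration cap
#' @return list: `domains`, `per_sample`, `excluded`, `iterations`
#' @export
call_mch_domains <- function(tracks, meta, elevation = 1.5, pseudo = 0.001,
                             penalty = NULL, scale = 1000,
                             min_len = 15000, min_bins = 3, max_iter = 25) {
  meta <- as.data.table(meta)
  stopifnot(all(meta$sample_id %in% names(tracks)))
  bin_size <- attr(tracks[[1]], "bin_size")
  controls <- meta[is_control == TRUE, sample_id]
  excluded <- empty_bed()
  iterations <- 0L
  if (length(controls)) {
    repeat {
      iterations <- iterations + 1L
      if (iterations > max_iter)
        stop("mCH exclusion loop failed to converge after ", max_iter,
             " iterations; ", nrow(excluded), " excluded regions, ",
             sum(excluded$end - excluded$start), " bases")
      before <- sum(excluded$end - excluded$start)
      found <- lapply(controls, function(sid) {
        ch <- segment_chunks(tracks[[sid]], excluded, penalty, scale)
        elevated_chunks(ch, elevation, pseudo)[, .(chrom, start, end)]
      })
      excluded <- bed_reduce(rbind(excluded, rbindlist(found)))
      if (sum(excluded$end - excluded$start) == before) break
    }
  }
  per_sample <- lapply(setNames(meta$sample_id, meta$sample_id),
                       function(sid) {
    ch <- segment_chunks(tracks[[sid]], excluded, penalty, scale)
    elevated_chunks(ch, elevation, pseudo)[, .(chrom, start, end)]
  })
  groups <- split(meta$sample_id, list(meta$tissue, meta$stage), drop = TRUE)
  kept <- list()
  for (g in groups) {
    doms <- if (length(g) >= 2)
      Reduce(bed_intersect, per_sample[g]) else per_sample[[g]]
    doms <- doms[end - start >= max(min_len, min_bins * bin_size)]
    kept[[length(kept) + 1]] <- doms
  }
  domains <- merge_domains(kept)
  list(domains = domains, per_sample = per_sample, excluded = excluded,
       iterations = iterations)
}

# length-weighted mean bin level over [a, b) on one chromosome
interval_track_level <- function(track_chr, a, b) {
  sel <- track_chr$end > a & track_chr$start < b
  if (!any(sel)) return(NA_real_)
  tr <- track_chr[sel]
  w <- pmin(tr$end, b) - pmax(tr$start, a)
  ok <- !is.na(tr$level)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * tr$level[ok]) / sum(w[ok])
}

#' mCH accumulation profiles of domains
#'
#' Per domain and sample, a length-50 vector: 20 5-kb bins upstream, 10
#' equal divisions of the domain body (fractional bins allowed), 20 5-kb
#' bins downstream, each divided by the mean level of the 40 flanking bins
#' (a pseudo-level replaces an all-zero flank mean). No-data values are
#' imputed with the flank mean (i.e. 1 after normalisation).
#'
#' @param domains BED table
#' @param tracks named list of 5-kb CH `LevelTrack`s
#' @param sample_ids samples to include (profiles are concatenated)
#' @param n_flank_bins,n_body_bins profile geometry (20 / 10)
#' @param pseudo fallback denominator for all-zero flanks
#' @return matrix, domains x (50 * length(sample_ids))
#' @export
mch_domain_profiles <- function(domains, tracks, sample_ids,
                                n_flank_bins = 20, n_body_bins = 10,
                                pseudo = 0.001) {
  bin_size <- attr(tracks[[1]], "bin_size")
  prof_one <- function(track, d) {
    tr <- track[chrom == d$chrom]
    up_starts <- d$start - bin_size * (n_flank_bins:1)
    dn_starts <- d$end + bin_size * (0:(n_flank_bins - 1))
    flank_vals <- vapply(c(up_starts, dn_starts), function(s)
      interval_track_level(tr, s, s + bin_size), numeric(1))
    body_edges <- seq(d$start, d$end, length.out = n_body_bins + 1)
    body_vals <- vapply(seq_len(n_body_bins), function(i)
      interval_track_level(tr, body_edges[i], body_edges[i + 1]), numeric(1))
    v <- c(flank_vals[seq_len(n_flank_bins)], body_vals,
           flank_vals[n_flank_bins + seq_len(n_flank_bins)])
    fm <- mean(flank_vals, na.rm = TRUE)
    if (!is.finite(fm)) fm <- 0
    v[is.na(v)] <- fm
    denom <- if (fm > 0) fm else pseudo
    v / denom
  }
  out <- matrix(NA_real_, nrow(domains),
                (2 * n_flank_bins + n_body_bins) * length(sample_ids))
  for (i in seq_len(nrow(domains))) {
    d <- as.list(domains[i])
    out[i, ] <- unlist(lapply(sample_ids, function(sid)
      prof_one(tracks[[sid]], d)))
  }
  out
}

#' k-means clustering of mCH-domain profiles
#'
#' @param profiles matrix from [mch_domain_profiles()]
#' @param k clusters (default 5)
#' @param seed RNG seed
#' @param nstart k-means restarts
#' @return integer cluster labels
#' @export
cluster_mch_domains <- function(profiles, k = 5, seed = 1, nstart = 20) {
  if (k >= nrow(profiles))
    stop("k exceeds the number of clusterable domains (need k < n)")
  set.seed(seed)
  kmeans(profiles, centers = k, nstart = nstart)$cluster
}

#' Relative expression z-scores of mCH-domain genes
#'
#' Per tissue, each expressed gene's TPM trajectory across stages is
#' z-scored (genes with no expression or zero variance are skipped); the
#' reported value per stage is the mean z of genes overlapping mCH domains
#' minus the mean z of genes outside any domain.
#'
#' @param tpm genes x samples matrix (rownames = genes)
#' @param meta `data.table` with sample_id, tissue, stage, stage_index;
#'   sample_id must match `colnames(tpm)`
#' @param domain_genes character vector of genes overlapping mCH domains
#' @return `data.table`: tissue, stage, relative_z, n_domain, n_outside
#' @export
mch_repression_zscores <- function(tpm, meta, domain_genes) {
  meta <- as.data.table(meta)
  out <- list()
  for (tis in unique(meta$tissue)) {
    sm <- meta[tissue == tis][order(stage_index)]
    cols <- sm$sample_id
    m <- tpm[, cols, drop = FALSE]
    sds <- apply(m, 1, sd)
    expressed <- rowSums(m) > 0 & sds > 0
    z <- (m[expressed, , drop = FALSE] -
            rowMeans(m[expressed, , drop = FALSE])) / sds[expressed]
    ing <- rownames(z) %in% domain_genes
    rel <- colMeans(z[ing, , drop = FALSE]) -
      colMeans(z[!ing, , drop = FALSE])
    out[[tis]] <- data.table(tissue = tis, stage = sm$stage,
                             relative_z = as.numeric(rel),
                             n_domain = sum(ing), n_outside = sum(!ing))
  }
  rbindlist(out)
}
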