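# DMS calling, DMS -> CG-DMR merging, the bulk-baseline tissue-specificity
# algorithm, effect sizes, loss/gain-of-mCG event accounting, CG-DMR
# categorisation, mCG~H3K27ac association and trajectory clustering.

#' Call differentially methylated sites (DMSs)
#'
#' Per CpG site, the statistic is the coverage-standardised root-mean-
#' square deviation of per-sample methylated fractions from the pooled
#' fraction (in chi-square form):
#' `T = sum_s cov_s * (f_s - fbar)^2 / (fbar * (1 - fbar))`.
#' The null distribution is obtained by permutation: methylated read
#' labels are reallocated across samples by sequential multivariate
#' hypergeometric draws, preserving each sample's coverage and the site's
#' total methylated count. Because the statistic is standardised, permuted
#' statistics are pooled across sites, giving p-value resolution
#' `1 / (n_sites * n_perm + 1)` so that Benjamini-Hochberg control at
#' genome scale is attainable. Sites passing the FDR cutoff become DMSs;
#' each is labelled with its hypo-sample set (samples more than
#' `hypo_delta` below the across-sample mean fraction).
#'
#' @param mc,cov integer matrices, sites x samples (strand-merged CpG
#'   counts, replicates combined); rownames/attributes are free-form but
#'   `chrom`/`pos` should be supplied
#' @param chrom,pos site coordinates (vectors, length nrow(mc))
#' @param n_perm permutations pooled across sites (default 100)
#' @param fdr BH false-discovery rate (default 0.01)
#' @param hypo_delta margin below the mean fraction defining a DMS's
#'   hypo-sample set (default 0.1)
#' @param seed RNG seed for the permutation draws
#' @return `data.table`: chrom, pos, stat, p, p_adj, is_dms, hypo
#'   (list-column of hypo sample indices), plus the fraction matrix as
#'   attribute `"fractions"`
#' @export
call_dms <- function(mc, cov, chrom, pos, n_perm = 100, fdr = 0.01,
                     hypo_delta = 0.1, seed = 1) {
  mc <- as.matrix(mc); cov <- as.matrix(cov)
  S <- ncol(mc)
  if (S < 2) stop("need at least 2 samples to call DMSs")
  nsite <- nrow(mc)
  stat_fun <- function(mcm) {
    tot_mc <- rowSums(mcm); tot_cov <- rowSums(cov)
    pbar <- tot_mc / tot_cov
    denom <- pbar * (1 - pbar)
    f <- mcm / cov
    T <- rowSums(cov * (f - pbar)^2, na.rm = TRUE) / denom
    T[!is.finite(T)] <- 0
    T
  }
  obs <- stat_fun(mc)

  set.seed(seed)
  tot_mc <- rowSums(mc); tot_cov <- rowSums(cov)
  null_stats <- numeric(nsite * n_perm)
  for (b in seq_len(n_perm)) {
    m_rem <- tot_mc; t_rem <- tot_cov
    perm <- matrix(0L, nsite, S)
    for (s in seq_len(S)) {
      if (s < S) {
        x <- rhyper(nsite, m_rem, t_rem - m_rem, cov[, s])
      } else {
        x <- m_rem
      }
      perm[, s] <- x
      m_rem <- m_rem - x
      t_rem <- t_rem - cov[, s]
    }
    null_stats[((b - 1) * nsite + 1):(b * nsite)] <- stat_fun(perm)
  }
  null_sorted <- sort(null_stats)
  n_null <- length(null_sorted)
  # p = (1 + #null >= obs) / (1 + n_null)
  p <- (n_null - findInterval(obs - 1e-12, null_sorted) + 1) / (n_null + 1)
  p_adj <- p.adjust(p, method = "BH")
  f <- mc / cov
  hypo <- lapply(seq_len(nsite), function(i) {
    fi <- f[i, ]
    which(mean(fi, na.rm = TRUE) - fi > hypo_delta)
  })
  out <- data.table(chrom = chrom, pos = pos, stat = obs, p = p,
                    p_adj = p_adj, is_dms = p_adj <= fdr, hypo = hypo)
  setattr(out, "fractions", f)
  out[]
}

#' Merge DMSs into CG-DMRs
#'
#' Adjacent DMSs merge when within `max_gap` bp (position difference
#' <= `max_gap`) and pattern-compatible: their hypo-sample sets intersect.
#' Blocks with fewer than `min_dms` DMSs are dropped. A block's interval
#' spans from the first DMS dyad to the last (BED half-open).
#'
#' @param dms output of [call_dms()], significant rows only are used
#' @param max_gap maximum distance between adjacent DMSs (default 250)
#' @param min_dms minimum DMSs per block (default 3)
#' @return BED `data.table` with `n_dms` and `hypo` (union over members)
#' @export
merge_dms_to_dmrs <- function(dms, max_gap = 250, min_dms = 3) {
  d <- as.data.table(dms)
  if ("is_dms" %in% names(d)) d <- d[is_dms == TRUE]
  if (!nrow(d)) return(data.table(chrom = character(), start = numeric(),
                                  end = numeric(), n_dms = integer(),
                                  hypo = list()))
  setorder(d, chrom, pos)
  n <- nrow(d)
  compatible <- c(FALSE, vapply(seq_len(n - 1), function(i) {
    d$chrom[i + 1] == d$chrom[i] &&
      (d$pos[i + 1] - d$pos[i]) <= max_gap &&
      length(intersect(d$hypo[[i]], d$hypo[[i + 1]])) > 0
  }, logical(1)))
  d[, block := cumsum(!compatible)]
  out <- d[, .(chrom = chrom[1], start = min(pos) - 1, end = max(pos) + 1,
               n_dms = .N, hypo = list(sort(unique(unlist(hypo))))),
           by = block]
  out[, block := NULL]
  out[n_dms >= min_dms]
}

#' Bulk-baseline outlier detection for one region
#'
#' Sorts the N sample levels, finds the narrowest window of
#' `ceiling(N/2)` consecutive ordered values (ties break to the smallest
#' start index; equal levels keep sample order), takes the window mean as
#' the baseline b, and flags samples at least `margin` below b as
#' hypomethylated.
#'
#' @param levels numeric vector of per-sample mCG levels (no missing
#'   values; drop such regions upstream)
#' @param margin hypomethylation margin (default 0.3)
#' @return object of class `BaselineResult`: list with `n`, `ordered`,
#'   `a` (0-based window offset), `bulk` (indices into the original
#'   vector), `b`, `hypo` (indices into the original vector)
#' @export
baseline_bulk <- function(levels, margin = 0.3) {
  if (anyNA(levels)) stop("missing levels; drop zero-coverage regions upstream")
  N <- length(levels)
  if (N < 2) stop("need at least 2 samples")
  w <- ceiling(N / 2)
  o <- order(levels)            # stable for ties
  x <- levels[o]
  ranges <- x[seq(w, N)] - x[seq(1, N - w + 1)]
  t <- which.min(ranges)        # smallest a on ties (which.min takes first)
  b <- mean(x[t:(t + w - 1)])
  hypo <- which(levels - b <= -margin)
  structure(list(n = N, ordered = x, a = t - 1L,
                 bulk = o[t:(t + w - 1)], b = b, hypo = hypo,
                 window_range = ranges[t], margin = margin),
            class = "BaselineResult")
}

#' CG-DMR effect size
#'
#' Absolute difference between the most hypomethylated sample and the bulk
#' baseline.
#'
#' @param levels per-sample mCG levels
#' @param baseline optional precomputed [baseline_bulk()] result
#' @export
effect_size <- function(levels, baseline = NULL) {
  if (is.null(baseline)) baseline <- baseline_bulk(levels)
  abs(min(levels) - baseline$b)
}

#' Tissue-specific calls for a matrix of region levels
#'
#' Applies [baseline_bulk()] row-wise. Rows with any missing level are
#' excluded (returned with NA results).
#'
#' @param level_mat regions x samples matrix of mCG levels
#' @param margin hypomethylation margin (default 0.3)
#' @return `data.table`: baseline, effect, hypo (list of sample indices),
#'   n_hypo, filtered flag
#' @export
tissue_specific_dmrs <- function(level_mat, margin = 0.3) {
  M <- nrow(level_mat)
  res <- data.table(baseline = rep(NA_real_, M), effect = NA_real_,
                    hypo = vector("list", M), n_hypo = NA_integer_,
                    filtered = FALSE)
  for (i in seq_len(M)) {
    lv <- level_mat[i, ]
    if (anyNA(lv)) { res$filtered[i] <- TRUE; next }
    bl <- baseline_bulk(lv, margin = margin)
    res$baseline[i] <- bl$b
    res$effect[i] <- effect_size(lv, bl)
    res$hypo[[i]] <- bl$hypo
    res$n_hypo[i] <- length(bl$hypo)
  }
  res[]
}

#' Count loss- and gain-of-mCG events along one trajectory
#'
#' A stage interval is the transition between two adjacent sampled stages.
#' A drop of at least `delta` is one loss event; a rise of at least
#' `delta` is one gain event. One region contributes at most one loss and
#' one gain per interval.
#'
#' @param trajectory per-stage mCG levels, chronological order
#' @param delta event threshold (default 0.1)
#' @return `data.table`: interval index, loss, gain (logical)
#' @export
count_mcg_events <- function(trajectory, delta = 0.1) {
  if (length(trajectory) < 2)
    return(data.table(interval = integer(0), loss = logical(0),
                      gain = logical(0)))
  d <- diff(trajectory)
  data.table(interval = seq_along(d), loss = d <= -delta, gain = d >= delta)
}

#' Categorize CG-DMRs
#'
#' Proximal categories by decreasing priority: CGI promoter, non-CGI
#' promoter, CGI, CGI shore. Remaining (distal) CG-DMRs: enhancer score
#' > `score_cutoff` makes a distal feDMR; within `flank_dist` of a distal
#' feDMR makes a flanking distal feDMR; tissue-specific hypomethylation
#' (effect >= `effect_min`) makes a primed distal feDMR; the rest are
#' unxDMRs, split by transposon overlap into te-unxDMRs and nte-unxDMRs.
#'
#' @param dmrs BED table of CG-DMRs
#' @param promoters,cgis,shores,transposons annotation BED tables
#'   (promoters are TSS +/- 2.5 kb; shores CGI +/- 2 kb)
#' @param enhancer_scores optional numeric vector (one per DMR, NA
#'   allowed); when absent and distal DMRs exist, the feDMR tier is
#'   skipped with a warning
#' @param effects per-DMR tissue-specificity effect sizes (NA allowed)
#' @param score_cutoff enhancer-score cutoff, strict (default 0.3)
#' @param flank_dist flanking distance in bp (default 1000)
#' @param effect_min primed-tier effect threshold (default 0.3)
#' @return factor of categories, one per DMR
#' @export
categorize_dmrs <- function(dmrs, promoters, cgis, shores, transposons,
                            enhancer_scores = NULL, effects = NULL,
                            score_cutoff = 0.3, flank_dist = 1000,
                            effect_min = 0.3) {
  lev <- c("CGI-promoter", "non-CGI-promoter", "CGI", "CGI-shore",
           "distal-feDMR", "flanking-distal-feDMR", "primed-distal-feDMR",
           "te-unxDMR", "nte-unxDMR")
  n <- nrow(dmrs)
  cat <- rep(NA_character_, n)
  cgi_prom <- promoters[bed_overlaps_any(promoters, cgis)]
  noncgi_prom <- promoters[!bed_overlaps_any(promoters, cgis)]
  hit <- function(track) if (nrow(track)) bed_overlaps_any(dmrs, track) else rep(FALSE, n)
  assign_if <- function(cond, label) cat[is.na(cat) & cond] <<- label
  assign_if(hit(cgi_prom), "CGI-promoter")
  assign_if(hit(noncgi_prom), "non-CGI-promoter")
  assign_if(hit(cgis), "CGI")
  assign_if(hit(shores), "CGI-shore")
  distal <- is.na(cat)
  if (any(distal)) {
    if (is.null(enhancer_scores)) {
      warning("no enhancer scores supplied; feDMR tier skipped")
      fed <- rep(FALSE, n)
    } else {
      fed <- !is.na(enhancer_scores) & enhancer_scores > score_cutoff
    }
    assign_if(distal & fed, "distal-feDMR")
    fed_regions <- dmrs[distal & fed]
    if (nrow(fed_regions)) {
      grown <- data.table(chrom = fed_regions$chrom,
                          start = pmax(0, fed_regions$start - flank_dist),
                          end = fed_regions$end + flank_dist)
      assign_if(is.na(cat) & bed_overlaps_any(dmrs, grown),
                "flanking-distal-feDMR")
    }
    ts <- if (is.null(effects)) rep(FALSE, n) else
      !is.na(effects) & effects >= effect_min
    assign_if(is.na(cat) & ts, "primed-distal-feDMR")
    te <- hit(transposons)
    assign_if(is.na(cat) & te, "te-unxDMR")
    assign_if(is.na(cat), "nte-unxDMR")
  }
  factor(cat, levels = lev)
}

#' Joint mCG / H3K27ac level table
#'
#' Rows: L (mCG <= 0.2), M (0.2, 0.6], H (> 0.6). Columns: H3K27ac
#' enrichment in \[0, 2\], (2, 4\], (4, 6\], (6, Inf); negative enrichment
#' falls in the first column.
#'
#' @param mcg,h3k27ac paired numeric vectors
#' @return 3 x 4 contingency table
#' @export
mcg_h3k27ac_association <- function(mcg, h3k27ac) {
  row <- cut(mcg, breaks = c(-Inf, 0.2, 0.6, Inf), labels = c("L", "M", "H"))
  col <- cut(pmax(h3k27ac, 0), breaks = c(-Inf, 2, 4, 6, Inf),
             labels = c("[0,2]", "(2,4]", "(4,6]", "(6,Inf)"))
  table(mcg = row, h3k27ac = col)
}

#' Normalize per-region H3K27ac dynamics
#'
#' Negative enrichment values are clamped to zero, then each row is
#' divided by its maximum; all-zero rows stay zero.
#'
#' @param m regions x stages matrix of enrichment values
#' @export
normalize_h3k27ac <- function(m) {
  m <- pmax(as.matrix(m), 0)
  mx <- apply(m, 1, max)
  mx[mx == 0] <- 1
  m / mx
}

#' k-means clustering of joint mCG / H3K27ac trajectories
#'
#' H3K27ac rows are normalised with [normalize_h3k27ac()] (making their
#' range comparable to mCG levels), concatenated with the mCG levels, and
#' clustered by k-means with a fixed seed.
#'
#' @param mcg,h3k27ac regions x stages matrices
#' @param k number of clusters
#' @param seed RNG seed
#' @param nstart k-means restarts (default 20)
#' @return integer cluster labels
#' @export
cluster_dmr_trajectories <- function(mcg, h3k27ac, k, seed = 1, nstart = 20) {
  if (k >= nrow(mcg))
    stop("k exceeds the number of clusterable regions (need k < n)")
  x <- cbind(as.matrix(mcg), normalize_h3k27ac(h3k27ac))
  set.seed(seed)
  kmeans(x, centers = k, nstart = nstart)$cluster
}
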