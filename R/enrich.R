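# Hypergeometric enrichment with BH correction, Monte-Carlo interval-
# shuffle overlap tests, and Monte-Carlo gene-set resampling tests.

#' Symmetrically extend regions to a target mean width
#'
#' Every region is extended by the same amount on both sides so that the
#' mean width reaches `target`; sets already at or above the target are
#' returned unchanged (extension only, no shrinking). Starts are clamped
#' at 0.
#'
#' @param regions BED table
#' @param target target mean width in bp (default 400)
#' @export
extend_to_mean_width <- function(regions, target = 400) {
  if (!nrow(regions)) return(regions)
  wbar <- mean(regions$end - regions$start)
  if (wbar >= target) return(copy(regions))
  e <- round((target - wbar) / 2)
  out <- copy(as.data.table(regions))
  out[, `:=`(start = pmax(0, start - e), end = end + e)]
  out[]
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= n_f)` where X counts foreground regions among the `n_f + n_b`
#' item-overlapping regions drawn from `N_f` foreground and `N_b`
#' background regions:
#' `sum_{x = n_f}^{n_f + n_b} C(N_f, x) C(N_b, n_t - x) / C(N_t, n_t)`.
#'
#' @param n_f,N_f overlapping / total foreground counts
#' @param n_b,N_b overlapping / total background counts
#' @return p-value(s); vectorised
#' @export
hypergeom_pvalue <- function(n_f, N_f, n_b, N_b) {
  phyper(n_f - 1, N_f, N_b, n_f + n_b, lower.tail = FALSE)
}

#' Motif (item) enrichment in foreground vs background regions
#'
#' Foreground and background are size-normalised by symmetric extension to
#' a common mean width, each item's occurrence intervals are overlapped
#' with both sets, the upper-tail hypergeometric p-value is computed per
#' item and BH-adjusted across items, and (optionally) items whose TF
#' expression is below `min_tpm` are dropped.
#'
#' @param foreground,background BED tables (disjoint sets of regions)
#' @param occurrences named list of BED tables, one per item (motif)
#' @param extend_to common mean width for size normalisation (400 bp;
#'   `NULL` disables)
#' @param fdr BH FDR cutoff stored as the `significant` flag (0.01)
#' @param tf_tpm optional named vector of TF expression values
#' @param min_tpm expression filter threshold (default 10)
#' @return `data.table`: item, N_f, N_b, n_f, n_b, p, p_adj, significant
#' @export
hypergeom_enrichment <- function(foreground, background, occurrences,
                                 extend_to = 400, fdr = 0.01,
                                 tf_tpm = NULL, min_tpm = 10) {
  if (!is.null(extend_to)) {
    foreground <- extend_to_mean_width(foreground, extend_to)
    background <- extend_to_mean_width(background, extend_to)
  }
  N_f <- nrow(foreground); N_b <- nrow(background)
  res <- rbindlist(lapply(names(occurrences), function(item) {
    occ <- occurrences[[item]]
    data.table(item = item, N_f = N_f, N_b = N_b,
               n_f = sum(bed_overlaps_any(foreground, occ)),
               n_b = sum(bed_overlaps_any(background, occ)))
  }))
  res[, p := hypergeom_pvalue(n_f, N_f, n_b, N_b)]
  if (!is.null(tf_tpm)) {
    keep <- names(occurrences) %in% names(tf_tpm)[tf_tpm >= min_tpm]
    res <- res[keep]
  }
  res[, p_adj := p.adjust(p, method = "BH")]
  res[, significant := p_adj <= fdr]
  res[]
}

# Monte-Carlo p-value: (sum I(obs <= perm) + 1) / (k + 1)
mc_pvalue <- function(obs, perm) {
  (sum(obs <= perm) + 1) / (length(perm) + 1)
}

new_mc_result <- function(observed, permuted) {
  structure(list(observed = observed, permuted = permuted,
                 fold = observed / mean(permuted),
                 p = mc_pvalue(observed, permuted)),
            class = "MCResult")
}

# usable placement space: per chromosome the gap-free intervals
usable_space <- function(chrom_lengths, gaps = NULL) {
  full <- data.table(chrom = names(chrom_lengths), start = 0,
                     end = as.numeric(chrom_lengths))
  if (!is.null(gaps) && nrow(gaps)) bed_setdiff(full, gaps) else full
}

#' Monte-Carlo interval-shuffle overlap test
#'
#' The feature set is re-placed `k` times uniformly at random in the
#' gap-free genome (length-preserving; each feature lands entirely within
#' one gap-free stretch; shuffled features may overlap each other), the
#' overlap statistic with `targets` is recomputed each time, and
#' `p = (sum I(x_obs <= x_i) + 1) / (k + 1)`.
#'
#' @param features,targets BED tables
#' @param chrom_lengths named chromosome lengths
#' @param gaps BED of assembly gaps excluded from placement
#' @param k permutations (default 1000)
#' @param seed RNG seed
#' @param statistic `"count"` (features overlapping any target) or
#'   `"bases"` (total overlapping bases)
#' @return object of class `MCResult`: observed, permuted, fold, p
#' @export
mc_overlap_test <- function(features, targets, chrom_lengths, gaps = NULL,
                            k = 1000, seed = 1,
                            statistic = c("count", "bases")) {
  statistic <- match.arg(statistic)
  space <- usable_space(chrom_lengths, gaps)
  setorder(space, chrom, start)
  widths <- features$end - features$start
  if (any(widths > max(space$end - space$start)))
    stop("a feature is longer than any gap-free stretch")
  # reduced targets per chromosome with prefix-coverage, so the statistic
  # needs only binary searches inside the permutation loop
  tred <- bed_reduce(targets)
  tmap <- lapply(split(tred, tred$chrom), function(t) {
    list(starts = t$start, ends = t$end, cum = cumsum(t$end - t$start))
  })
  stat_fun <- function(chrom, start, end) {
    tot <- 0
    for (cn in unique(chrom)) {
      t <- tmap[[cn]]
      if (is.null(t)) next
      sel <- chrom == cn
      s <- start[sel]; e <- end[sel]
      if (statistic == "count") {
        i <- findInterval(s, t$starts)
        hit <- (i >= 1 & t$ends[pmax(i, 1)] > s) |
          (i < length(t$starts) & t$starts[pmin(i + 1, length(t$starts))] < e)
        tot <- tot + sum(hit)
      } else {
        cov_at <- function(x) {
          i <- findInterval(x, t$starts)
          ifelse(i == 0, 0,
                 t$cum[pmax(i, 1)] -
                   pmax(0, t$ends[pmax(i, 1)] - x))
        }
        tot <- tot + sum(cov_at(e) - cov_at(s))
      }
    }
    tot
  }
  observed <- stat_fun(features$chrom, features$start, features$end)
  # per feature width, placement slots available in each usable interval
  ivl_len <- space$end - space$start
  slot_cums <- lapply(widths, function(w) cumsum(pmax(0, ivl_len - w + 1)))
  set.seed(seed)
  permuted <- numeric(k)
  nf <- length(widths)
  for (i in seq_len(k)) {
    starts <- numeric(nf); chroms <- character(nf)
    u <- runif(nf)
    for (j in seq_len(nf)) {
      cums <- slot_cums[[j]]
      tot <- cums[length(cums)]
      pick <- u[j] * tot
      ci <- findInterval(pick, cums, left.open = TRUE) + 1
      slots_ci <- cums[ci] - c(0, cums)[ci]
      offset <- min(floor(pick - c(0, cums)[ci]), slots_ci - 1)
      chroms[j] <- space$chrom[ci]
      starts[j] <- space$start[ci] + offset
    }
    permuted[i] <- stat_fun(chroms, starts, starts + widths)
  }
  new_mc_result(observed, permuted)
}

#' Monte-Carlo gene-set resampling test
#'
#' `x_obs` is the overlap of the query set with the property set; each
#' permutation draws `|query|` genes uniformly without replacement from
#' the universe. Fold enrichment is `x_obs` over the mean permuted
#' overlap.
#'
#' @param query,universe,property character vectors of gene names; the
#'   query must be a subset of the universe
#' @param k permutations (default 1000)
#' @param seed RNG seed
#' @return object of class `MCResult`
#' @export
mc_geneset_test <- function(query, universe, property, k = 1000, seed = 1) {
  if (length(query) > length(universe))
    stop("query is larger than the universe")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  in_prop <- universe %in% property
  observed <- sum(query %in% property)
  set.seed(seed)
  permuted <- vapply(seq_len(k), function(i)
    sum(in_prop[sample.int(length(universe), length(query))]), numeric(1))
  new_mc_result(observed, permuted)
}

#' @export
print.MCResult <- function(x, ...) {
  cat("Monte-Carlo test: observed =", x$observed,
      "| mean permuted =", signif(mean(x$permuted), 4),
      "| fold =", signif(x$fold, 4),
      "| p =", signif(x$p, 4), paste0("(k = ", length(x$permuted), ")\n"))
  invisible(x)
}
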