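# Methylation levels, binned level tracks, the significant-mCH binomial
# test and sequence-context tallies.

#' Methylation level with non-conversion correction
#'
#' level = max(0, mc_sum / cov_sum - nonconversion). The level of a region
#' always pools counts before dividing (a count-weighted mean of per-site
#' fractions), never averages per-site levels. Zero coverage yields NA,
#' never 0.
#'
#' @param mc_sum methylated basecall count(s)
#' @param cov_sum total basecall count(s)
#' @param nonconversion bisulfite non-conversion rate
#' @return numeric level(s) in \[0, 1\], NA where cov_sum = 0
#' @export
methylation_level <- function(mc_sum, cov_sum, nonconversion = 0) {
  out <- pmax(0, mc_sum / cov_sum - nonconversion)
  out[cov_sum == 0] <- NA_real_
  out
}

#' Pooled methylation level of sites in a region
#' @param sites allc table (already subset to the region/context)
#' @param nonconversion non-conversion rate
#' @export
region_level <- function(sites, nonconversion = 0) {
  methylation_level(sum(sites$mc), sum(sites$cov), nonconversion)
}

#' Non-overlapping binned level track
#'
#' Bins tile each chromosome. A bin is no-data (level NA) when it has
#' fewer than `min_sites` sites, when fewer than `min_covered_fraction` of
#' its sites reach `cov_threshold` reads, or when it has no reads at all.
#' The bin level pools counts across its sites and subtracts the
#' non-conversion rate.
#'
#' @param sites allc table, strand-merged for CG work
#' @param bin_size bin width in bp (> 0)
#' @param chrom_lengths named chromosome lengths (defines the tiling)
#' @param nonconversion non-conversion rate
#' @param min_sites minimum sites per bin (default 1)
#' @param min_covered_fraction minimum fraction of sites with
#'   cov >= `cov_threshold` (default 0, i.e. not applied)
#' @param cov_threshold per-site coverage threshold (default 10)
#' @param context label stored on the track ("CG" or "CH")
#' @return `data.table` of class `LevelTrack`: chrom, start, end, level,
#'   n_sites, frac_cov, mc, cov
#' @export
binned_levels <- function(sites, bin_size, chrom_lengths, nonconversion = 0,
                          min_sites = 1, min_covered_fraction = 0,
                          cov_threshold = 10, context = "CG") {
  if (bin_size <= 0) stop("bin_size must be > 0")
  grid <- rbindlist(lapply(names(chrom_lengths), function(cn) {
    starts <- seq(0, chrom_lengths[[cn]] - 1, by = bin_size)
    data.table(chrom = cn, start = starts,
               end = pmin(starts + bin_size, chrom_lengths[[cn]]))
  }))
  s <- as.data.table(sites)[, .(chrom, pos, mc, cov)]
  s[, start := ((pos - 1) %/% bin_size) * bin_size]
  agg <- s[, .(mc = sum(mc), cov = sum(cov), n_sites = .N,
               frac_cov = mean(cov >= cov_threshold)), by = .(chrom, start)]
  out <- merge(grid, agg, by = c("chrom", "start"), all.x = TRUE)
  out[is.na(n_sites), `:=`(mc = 0L, cov = 0L, n_sites = 0L, frac_cov = 0)]
  out[, level := methylation_level(mc, cov, nonconversion)]
  out[n_sites < min_sites | frac_cov < min_covered_fraction, level := NA_real_]
  setorder(out, chrom, start)
  setattr(out, "bin_size", bin_size)
  setattr(out, "context", context)
  setattr(out, "class", c("LevelTrack", class(out)))
  out[]
}

#' Significantly methylated CH sites (binomial test, per-context BH)
#'
#' Per site, p = P(X >= mc | n = cov, p = nonconversion), the upper tail
#' of the binomial under the no-methylation (pure non-conversion) null.
#' Benjamini-Hochberg FDR control is applied independently within each
#' trinucleotide context; the per-context p-value cutoff is the largest
#' raw p among rejected sites.
#'
#' @param sites CH allc table (each site cov >= 1)
#' @param nonconversion non-conversion rate, must be in (0, 1)
#' @param fdr FDR level (default 0.01)
#' @return list: `sites` (input plus p, p_adj, significant),
#'   `cutoffs` (named per-context p cutoff)
#' @export
mch_site_test <- function(sites, nonconversion, fdr = 0.01) {
  if (nonconversion <= 0 || nonconversion >= 1)
    stop("nonconversion must be in (0, 1); supply a floor for fully ",
         "converted libraries")
  out <- as.data.table(sites)
  out[, p := pbinom(mc - 1, cov, nonconversion, lower.tail = FALSE)]
  out[, p_adj := p.adjust(p, method = "BH"), by = context]
  out[, significant := p_adj <= fdr]
  cutoffs <- out[, .(cutoff = if (any(significant)) max(p[significant]) else 0),
                 by = context]
  list(sites = out[],
       cutoffs = setNames(cutoffs$cutoff, cutoffs$context))
}

#' Position-specific base counts around significant mCH sites
#'
#' Tallies base occurrences per flanking position from fixed-width
#' sequence windows centred on each site (the site's cytosine at position
#' 0). Windows of the wrong width (e.g. sites too close to a chromosome
#' edge) are skipped with a warning. Column sums over A/C/G/T equal the
#' number of counted sites at every position.
#'
#' @param flanks character vector of sequence windows, all of odd length
#'   (e.g. 11 for +/- 5 bp)
#' @param width expected window width (default 11)
#' @return integer matrix, rows A/C/G/T, columns positions -w..+w
#' @export
context_preference <- function(flanks, width = 11) {
  half <- (width - 1) / 2
  counts <- matrix(0L, nrow = 4, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"),
                                   as.character(seq(-half, half))))
  if (!length(flanks)) return(counts)
  ok <- !is.na(flanks) & nchar(flanks) == width
  if (any(!ok)) warning(sum(!ok), " site(s) skipped: window not ", width, " bp")
  flanks <- toupper(flanks[ok])
  if (!length(flanks)) return(counts)
  m <- do.call(rbind, strsplit(flanks, "", fixed = TRUE))
  for (j in seq_len(width)) {
    tb <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    counts[, j] <- as.integer(tb)
  }
  counts
}
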