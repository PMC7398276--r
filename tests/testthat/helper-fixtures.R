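suppressMessages(library(data.table))

# small genome + truth + design shared by several tests
small_genome <- function(seed = 11, len = c(chr1 = 2e6)) {
  generate_genome(len, seed = seed)
}

small_truth <- function(genome, design = make_design(), config = list()) {
  plant_truth(genome, design,
              utils::modifyList(list(n_dmrs_per_tissue = 2, n_dmvs = 2,
                                     n_pmds = 1, pmd_widths = c(2e5, 2e5),
                                     n_mch_domains = 2, n_artefacts = 1,
                                     seed = 13), config))
}

# hand-built 5-kb level track for domain tests
make_track <- function(levels, bin_size = 5000, chrom = "chr1",
                       context = "CH") {
  n <- length(levels)
  tr <- data.table(chrom = chrom, start = (seq_len(n) - 1) * bin_size,
                   end = seq_len(n) * bin_size, level = levels,
                   n_sites = 600L, frac_cov = 1,
                   mc = 0L, cov = 1000L)
  setattr(tr, "bin_size", bin_size)
  setattr(tr, "context", context)
  setattr(tr, "class", c("LevelTrack", class(tr)))
  tr
}

# adjusted Rand index via mclust (independent of the package's clustering)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force nearest-TSS oracle (independent O(n*m) enumeration)
nearest_tss_oracle <- function(regions, tss) {
  vapply(seq_len(nrow(regions)), function(i) {
    t <- tss[tss$chrom == regions$chrom[i], ]
    t0 <- t$pos - 1
    d <- ifelse(t0 >= regions$start[i] & t0 < regions$end[i], 0,
                ifelse(t0 < regions$start[i], regions$start[i] - t0,
                       t0 - (regions$end[i] - 1)))
    ord <- order(d, t$pos)
    t$gene[ord[1]]
  }, character(1))
}

# exhaustive-window baseline oracle: enumerate every window explicitly
baseline_oracle <- function(levels, margin = 0.3) {
  N <- length(levels)
  w <- ceiling(N / 2)
  x <- sort(levels)
  best_a <- NA; best_range <- Inf
  for (a in 0:(N - w)) {
    r <- x[a + w] - x[a + 1]
    if (r < best_range) { best_range <- r; best_a <- a }  # ties keep smaller a
  }
  b <- mean(x[(best_a + 1):(best_a + w)])
  list(a = best_a, b = b, hypo = which(levels - b <= -margin))
}

# exact binomial upper tail by direct summation
binom_tail_oracle <- function(mc, cov, p) {
  if (mc <= 0) return(1)
  sum(vapply(mc:cov, function(k) choose(cov, k) * p^k * (1 - p)^(cov - k),
             numeric(1)))
}

# exact hypergeometric upper tail by direct enumeration
hyper_tail_oracle <- function(n_f, N_f, n_b, N_b) {
  n_t <- n_f + n_b
  xs <- n_f:min(n_t, N_f)
  if (n_f <= 0) return(1)
  sum(choose(N_f, xs) * choose(N_b, n_t - xs)) / choose(N_f + N_b, n_t)
}
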