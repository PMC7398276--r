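test_that("allc files round-trip and tolerate the optional 7th column", {
  dt <- data.table(chrom = "chr1", pos = c(1000L, 1001L, 1500L),
                   strand = c("+", "-", "+"),
                   context = c("CGA", "CGT", "CAC"),
                   mc = c(5L, 2L, 0L), cov = c(10L, 10L, 8L))
  path <- tempfile(fileext = ".tsv")
  write_allc(dt, path)
  back <- read_allc(path)
  expect_equal(as.data.frame(back), as.data.frame(dt))
  # byte-identical body on re-write
  path2 <- tempfile(fileext = ".tsv")
  write_allc(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # gzip transparently
  pgz <- tempfile(fileext = ".tsv.gz")
  write_allc(dt, pgz)
  expect_equal(as.data.frame(read_allc(pgz)), as.data.frame(dt))
  # 7th 0/1 column accepted and ignored
  lines <- paste(dt$chrom, dt$pos, dt$strand, dt$context, dt$mc, dt$cov, 1,
                 sep = "\t")
  p7 <- tempfile(fileext = ".tsv")
  writeLines(lines, p7)
  expect_equal(as.data.frame(read_allc(p7)), as.data.frame(dt))
})

test_that("malformed allc rows fail with the offending line number", {
  bad <- data.table(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                    context = "CGA", mc = c(1L, 11L), cov = c(5L, 10L))
  p <- tempfile(fileext = ".tsv")
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_error(read_allc(p), "line 2")
  bad2 <- copy(bad)[, mc := c(1L, 2L)][1, pos := -5L]
  write.table(bad2, p, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_error(read_allc(p), "line 1")
  bad3 <- copy(bad)[, mc := c(1L, 2L)][2, strand := "*"]
  write.table(bad3, p, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_error(read_allc(p), "strand at line 2")
})

test_that("CpG dyads merge onto the plus strand and conserve counts", {
  dt <- data.table(
    chrom = "chr1", pos = c(100L, 101L, 120L, 150L),
    strand = c("+", "-", "+", "+"),
    context = c("CGA", "CGT", "CGC", "CAC"),
    mc = c(3L, 2L, 1L, 4L), cov = c(10L, 10L, 6L, 9L))
  m <- merge_strand_cg(dt)
  dyad <- m[pos == 100]
  expect_equal(dyad$mc, 5L)      # 3 + 2
  expect_equal(dyad$cov, 20L)    # 10 + 10
  expect_false(101 %in% m$pos)
  # lone + strand CG passes through unchanged
  expect_equal(m[pos == 120, .(mc, cov)], dt[pos == 120, .(mc, cov)])
  # CH site untouched
  expect_equal(m[pos == 150, .(strand, mc, cov)],
               dt[pos == 150, .(strand, mc, cov)])
  # conservation on a random table
  set.seed(4)
  n <- 500
  pos <- sort(sample.int(1e5, n))
  rnd <- data.table(chrom = "chr1", pos = pos,
                    strand = sample(c("+", "-"), n, TRUE),
                    context = sample(c("CGA", "CGT", "CAC", "CTG"), n, TRUE),
                    cov = rpois(n, 20))
  rnd[, mc := rbinom(n, cov, 0.5)]
  mr <- merge_strand_cg(rnd)
  expect_equal(sum(mr$mc), sum(rnd$mc))
  expect_equal(sum(mr$cov), sum(rnd$cov))
})

test_that("QC reports non-conversion, coverage and replicate concordance", {
  lam <- data.table(chrom = "lambda", pos = 1:100, strand = "+",
                    context = "CAA", mc = 0L, cov = 100L)
  lam$mc[1] <- 50L
  allc <- data.table(chrom = "chr1", pos = c(10L, 11L), strand = c("+", "-"),
                     context = c("CGA", "CGT"), mc = c(5L, 5L),
                     cov = c(10L, 10L))
  qc <- compute_qc(allc, lam)
  expect_equal(qc$nonconversion_rate, 50 / 10000)
  expect_equal(qc$mean_coverage, 20)  # one strand-merged dyad
  # identical replicates at all qualifying sites give r = 1
  a <- data.table(chrom = "chr1", pos = seq(10L, 200L, by = 10L),
                  strand = "+", context = "CGA", cov = 20L)
  set.seed(1); a[, mc := rbinom(.N, cov, runif(.N))]
  qc2 <- compute_qc(a, lam, partner = copy(a))
  expect_equal(qc2$replicate_r, 1.0)
  expect_error(compute_qc(allc, lam[0]), "lambda")
})

test_that("replicates simulated from one truth at 30x correlate above 0.8", {
  g <- generate_genome(c(chr1 = 4e5), seed = 17)
  d <- make_design(tissues = c("forebrain", "heart"), replicates = 2)
  t <- small_truth(g, d, config = list(n_pmds = 0, n_mch_domains = 0,
                                       n_artefacts = 0))
  s1 <- simulate_counts(g, t, as.list(d[1]), seed = 100)
  s2 <- simulate_counts(g, t, as.list(d[2]), seed = 200)
  qc <- compute_qc(s1$allc, s1$lambda, partner = s2$allc)
  expect_gt(qc$replicate_r, 0.8)
})

test_that("transposon mappability filter applies both rules inclusively", {
  te <- bed(chrom = "chr1", start = c(0, 1000, 2000), end = c(500, 1500, 2500))
  # TE1: 1 CG site; TE2: 5 sites, 3 covered (60%, boundary); TE3: 5 sites,
  # 2 covered
  mk <- function(cov_vals) data.table(
    chrom = "chr1",
    pos = c(100L, 1050L, 1100L, 1150L, 1200L, 1250L,
            2050L, 2100L, 2150L, 2200L, 2250L),
    strand = "+", context = "CGA", mc = 0L, cov = cov_vals)
  covs <- c(20L, 20L, 20L, 20L, 5L, 5L, 20L, 20L, 5L, 5L, 5L)
  out <- filter_mappable_transposons(te, list(mk(covs), mk(covs)))
  expect_equal(out$start, 1000)
  # a sample with low coverage at a shared site breaks the 60% rule
  covs2 <- covs; covs2[4] <- 3L
  out2 <- filter_mappable_transposons(te, list(mk(covs), mk(covs2)))
  expect_equal(nrow(out2), 0)
})

test_that("regions link to the nearest expressed TSS with low-coordinate ties", {
  tss <- data.table(chrom = "chr1", pos = c(150L, 10000L),
                    gene = c("gA", "gB"))
  r <- bed(chrom = "chr1", start = 100, end = 200)
  expect_equal(link_regions_to_genes(r, tss)$gene, "gA")
  expect_equal(link_regions_to_genes(r, tss)$distance, 0)
  # equidistant TSSs break to the lower coordinate: both 50 bp away
  tss2 <- data.table(chrom = "chr1", pos = c(51L, 250L), gene = c("lo", "hi"))
  r2 <- bed(chrom = "chr1", start = 100, end = 200)
  expect_equal(link_regions_to_genes(r2, tss2)$gene, "lo")
  expect_error(link_regions_to_genes(r2, tss2[0]), "empty")
})

test_that("nearest-TSS mapping matches the brute-force oracle", {
  set.seed(23)
  tss <- data.table(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                    pos = sample.int(1e6, 60),
                    gene = sprintf("g%02d", 1:60))
  starts <- sample.int(1e6 - 500, 1000)
  regions <- bed(chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                 start = starts, end = starts + sample(50:400, 1000, TRUE))
  got <- link_regions_to_genes(regions, tss)
  expect_equal(got$gene, nearest_tss_oracle(regions, tss))
})

test_that("expressed-gene filter keeps the 10% boundary and drops junk names", {
  tpm <- matrix(0, 5, 10,
                dimnames = list(c("Sox2", "Gm5123", "Gmab", "Rik1", "zero"),
                                NULL))
  tpm["Sox2", 1] <- 5          # 1 of 10 samples = boundary, kept
  tpm["Gm5123", ] <- 3
  tpm["Gmab", ] <- 3
  tpm["Rik1", ] <- 3
  expect_setequal(filter_expressed_genes(tpm),
                  c("Sox2", "Gm5123", "Gmab", "Rik1"))
  # 'Gm' needs a following digit to be junk; 'Rik'-prefixed names are junk
  expect_setequal(filter_expressed_genes(tpm, ontology_clean = TRUE),
                  c("Sox2", "Gmab"))
  expect_error(filter_expressed_genes(tpm[, 0]), "sample")
})
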