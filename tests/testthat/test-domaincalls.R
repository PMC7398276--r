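test_that("large hypo blocks merge within 1 kb and keep >= 2 kb", {
  d <- bed("chr1", c(0, 1800), c(900, 2700))      # 900-bp gap
  out <- call_large_hypo(d)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 0); expect_equal(out$end, 2700)
  expect_equal(nrow(call_large_hypo(bed("chr1", 0, 1500))), 0)  # < 2 kb
  d2 <- bed("chr1", c(0, 3001), c(2000, 5500))    # 1001-bp gap: no merge
  out2 <- call_large_hypo(d2)
  expect_equal(nrow(out2), 2)
})

test_that("DMV runs skip no-data bins without counting them", {
  lv <- function(v) make_track(v, bin_size = 1000)
  # five consecutive hypo bins in both replicates
  t1 <- lv(c(0.8, 0.10, 0.10, 0.10, 0.10, 0.10, 0.8))
  out <- call_dmvs(list(t1, copy(t1)))
  expect_equal(nrow(out), 1)
  expect_equal(out$end - out$start, 5000)
  # four bins are not enough
  t2 <- lv(c(0.8, 0.10, 0.10, 0.10, 0.10, 0.8))
  expect_equal(nrow(call_dmvs(list(t2, copy(t2)))), 0)
  # a no-data bin inside the run is skipped but does not break it
  t3 <- lv(c(0.8, 0.1, 0.1, NA, 0.1, 0.1, 0.1, 0.8))
  out3 <- call_dmvs(list(t3, copy(t3)))
  expect_equal(nrow(out3), 1)
  expect_equal(out3$end - out3$start, 6000)  # block spans the gap
  # replicate reconciliation: a block in one replicate only is dropped
  t4 <- lv(rep(0.8, 8))
  expect_equal(nrow(call_dmvs(list(t3, t4))), 0)
  expect_warning(call_dmvs(list(t3)), "single replicate")
})

test_that("PMD percentile features summarise per-site fractions", {
  sites <- data.table(chrom = "chr1", pos = seq(5L, 9995L, by = 10L),
                      strand = "+", context = "CGA", cov = 20L)
  sites[, mc := 10L]                      # every site at fraction 0.5
  f <- pmd_features(sites, c(chr1 = 10000), bin_size = 10000)
  expect_equal(unname(f$features[1, ]), rep(0.5, 19))
  # fewer than 10 sites -> no-feature sentinel
  f2 <- pmd_features(sites[1:9], c(chr1 = 10000), bin_size = 10000)
  expect_true(all(is.na(f2$features[1, ])))
  # site order must not matter
  f3 <- pmd_features(sites[sample.int(nrow(sites))], c(chr1 = 10000),
                     bin_size = 10000)
  expect_equal(f3$features, f$features)
  # low-coverage sites and excluded regions are removed first
  sites2 <- copy(sites)[1:500, `:=`(mc = 0L, cov = 3L)]
  f4 <- pmd_features(sites2, c(chr1 = 10000), cov_min = 5)
  expect_equal(unname(f4$features[1, ]), rep(0.5, 19))
  f5 <- pmd_features(sites, c(chr1 = 10000),
                     exclude = bed("chr1", 0, 10000))
  expect_true(all(is.na(f5$features)))
})

test_that("PMD calling recovers planted intermediate-methylation blocks", {
  set.seed(31)
  n_bins <- 100                      # 1 Mb at 10-kb bins
  truth_pmd <- bed("chr1", 300000, 600000)
  mk_rep <- function(seed) {
    set.seed(seed)
    sites <- data.table(chrom = "chr1",
                        pos = seq(5L, 999995L, by = 50L),
                        strand = "+", context = "CGA")
    sites[, cov := rpois(.N, 60)]
    m <- ifelse(sites$pos > 300000 & sites$pos <= 600000, 0.5, 0.85)
    sites[, mc := rbinom(.N, cov, m)]
    pmd_features(sites, c(chr1 = 1e6))
  }
  r1 <- mk_rep(1); r2 <- mk_rep(2)
  frac <- bed_overlap_bases(r1$bins, truth_pmd) / (r1$bins$end - r1$bins$start)
  res <- call_pmds(r1$features, frac >= 0.5, list(r1, r2), ntree = 200)
  expect_gte(jaccard_bases(res$pmds, truth_pmd), 0.9)
  # a 90-kb predicted block would be dropped by the length filter
  short <- list(bins = r1$bins[1:9], features = r1$features[1:9, ])
  res2 <- call_pmds(r1$features, frac >= 0.5,
                    list(list(bins = r1$bins[31:39],
                              features = r1$features[31:39, ])))
  expect_equal(nrow(res2$pmds), 0)
})

test_that("chunk elevation rule uses the 1.5x threshold with pseudo-level", {
  ch <- data.table(chrom = "chr1", start = c(0, 50000, 100000),
                   end = c(50000, 100000, 150000),
                   level = c(0.01, 0.02, 0.01), n_bins = 10L)
  out <- elevated_chunks(ch)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 50000)
  ch2 <- copy(ch)[2, level := 0.014]       # 1.27x < 1.5x
  expect_equal(nrow(elevated_chunks(ch2)), 0)
  # terminal chunks are never called
  ch3 <- copy(ch)[1, level := 0.05]
  expect_false(0 %in% elevated_chunks(ch3)$start)
})

test_that("mCH domain calling excludes control artefacts then recovers domains", {
  bin <- 5000
  n <- 400                                  # 2 Mb of 5-kb bins
  dom_bins <- 101:110                       # planted domain: 50 kb
  art_bins <- 301:306                       # artefact: shows up everywhere
  mk <- function(base, dom_factor, art = 0.04, seed) {
    set.seed(seed)
    lv <- pmax(0, rnorm(n, base, 0.0005))
    lv[dom_bins] <- base * dom_factor + rnorm(length(dom_bins), 0, 0.0005)
    lv[art_bins] <- art
    make_track(lv, bin_size = bin)
  }
  meta <- data.table(
    sample_id = c("c1", "c2", "s1", "s2"),
    tissue = c("fb", "fb", "fb", "fb"),
    stage = c("E10.5", "E10.5", "P0", "P0"),
    replicate = c(1, 2, 1, 2),
    is_control = c(TRUE, TRUE, FALSE, FALSE))
  tracks <- list(c1 = mk(0.0002, 1, seed = 1), c2 = mk(0.0002, 1, seed = 2),
                 s1 = mk(0.015, 2, seed = 3), s2 = mk(0.015, 2, seed = 4))
  res <- call_mch_domains(tracks, meta)
  expect_gte(res$iterations, 2)
  # artefact region excluded, not called
  art_bed <- bed("chr1", (min(art_bins) - 1) * bin, max(art_bins) * bin)
  expect_true(any(bed_overlaps_any(art_bed, res$excluded)))
  expect_equal(sum(bed_overlap_bases(res$domains, art_bed)), 0)
  # planted domain recovered in both replicates
  dom_bed <- bed("chr1", (min(dom_bins) - 1) * bin, max(dom_bins) * bin)
  expect_gte(jaccard_bases(res$domains, dom_bed), 0.8)
  # domains respect the 15-kb / 3-bin minima by construction
  expect_true(all(res$domains$end - res$domains$start >= 15000))
})

test_that("mCH profiles are flank-normalised length-50 vectors", {
  flat <- make_track(rep(0.01, 500))
  doms <- bed("chr1", 1000000, 1050000)
  p <- mch_domain_profiles(doms, list(s = flat), "s")
  expect_equal(ncol(p), 50)
  expect_equal(unname(p[1, ]), rep(1, 50))
  # a domain at twice its flanks: body 2, flanks 1
  lv <- rep(0.01, 500); lv[201:210] <- 0.02
  tr <- make_track(lv)
  p2 <- mch_domain_profiles(bed("chr1", 1000000, 1050000),
                            list(s = tr), "s")
  expect_equal(unname(p2[1, 21:30]), rep(2, 10), tolerance = 1e-6)
  expect_equal(unname(p2[1, 1:20]), rep(1, 20), tolerance = 1e-6)
  # short domains still divide into 10 fractional parts
  p3 <- mch_domain_profiles(bed("chr1", 1000000, 1020000),
                            list(s = flat), "s")
  expect_equal(ncol(p3), 50)
  expect_false(anyNA(p3))
})

test_that("planted profile archetypes cluster perfectly", {
  set.seed(41)
  a <- c(rep(1, 20), rep(3, 10), rep(1, 20))
  b <- c(rep(1, 20), seq(1, 4, length.out = 10), rep(1, 20))
  profs <- rbind(t(replicate(10, a + rnorm(50, 0, 0.05))),
                 t(replicate(10, b + rnorm(50, 0, 0.05))))
  cl <- cluster_mch_domains(profs, k = 2, seed = 5)
  expect_equal(ari(cl, rep(1:2, each = 10)), 1)
  expect_error(cluster_mch_domains(profs, k = 50), "exceeds")
})

test_that("repression z-scores contrast domain genes against the rest", {
  meta <- data.table(sample_id = paste0("fb_", 1:4), tissue = "fb",
                     stage = paste0("S", 1:4), stage_index = 1:4)
  # identical dynamics inside and outside: relative z is zero everywhere
  tpm <- matrix(rep(c(8, 6, 4, 2), each = 20), 20, 4, byrow = FALSE,
                dimnames = list(sprintf("g%02d", 1:20), meta$sample_id))
  tpm <- t(apply(tpm, 1, function(x) c(8, 6, 4, 2)))
  colnames(tpm) <- meta$sample_id
  rz <- mch_repression_zscores(tpm, meta, domain_genes = c("g01", "g02"))
  expect_equal(rz$relative_z, rep(0, 4), tolerance = 1e-12)
  # declining domain genes against flat outsiders: negative late, positive early
  tpm2 <- tpm
  tpm2[3:20, ] <- 5 + matrix(rnorm(18 * 4, 0, 0.01), 18, 4)
  rz2 <- mch_repression_zscores(tpm2, meta, domain_genes = c("g01", "g02"))
  expect_lt(rz2$relative_z[4], 0)
  expect_gt(rz2$relative_z[1], 0)
})

test_that("a planted repression trajectory is recovered at n = 500", {
  set.seed(51)
  n <- 500
  stages <- 4
  meta <- data.table(sample_id = paste0("fb_", 1:stages), tissue = "fb",
                     stage = paste0("S", 1:stages), stage_index = 1:stages)
  # outside genes: independent noise around a flat mean (E[z] = 0 per stage);
  # domain genes: a shared declining trajectory whose z-score profile is
  # known in closed form
  traj <- c(10, 9, 7, 4)
  expected_z <- (traj - mean(traj)) / sd(traj)
  base <- matrix(rnorm(n * stages, 10, 1), n, stages,
                 dimnames = list(sprintf("g%03d", 1:n), meta$sample_id))
  dom <- sprintf("g%03d", 1:250)
  base[dom, ] <- matrix(traj, 250, stages, byrow = TRUE) +
    rnorm(250 * stages, 0, 0.01)
  rz <- mch_repression_zscores(base, meta, dom)
  expect_equal(rz$relative_z, expected_z, tolerance = 0.1)
  expect_lt(rz$relative_z[stages], -1)
})
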