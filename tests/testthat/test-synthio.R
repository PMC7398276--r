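test_that("genome generation is deterministic and density-faithful", {
  g1 <- generate_genome(c(chr1 = 1e6), cg_density = 0.01, seed = 7)
  g2 <- generate_genome(c(chr1 = 1e6), cg_density = 0.01, seed = 7)
  expect_identical(g1$cg, g2$cg)
  expect_identical(g1$ch, g2$ch)
  expect_identical(g1$annotations, g2$annotations)
  g3 <- generate_genome(c(chr1 = 1e6), cg_density = 0.01, seed = 8)
  expect_false(identical(g1$cg, g3$cg))

  expect_equal(nrow(g1$cg), 10000)        # density * length
  expect_false(anyDuplicated(g1$cg$pos) > 0)

  g0 <- generate_genome(c(chr1 = 1e5), cg_density = 0, ch_density = 0,
                        seed = 1)
  expect_equal(nrow(g0$cg), 0)
  expect_equal(nrow(g0$ch), 0)
  expect_error(generate_genome(c(chr1 = 0)), "positive")
})

test_that("CG and CH site sets are disjoint and sorted", {
  g <- small_genome()
  expect_true(all(diff(g$cg$pos) > 0))
  expect_true(all(diff(g$ch$pos) > 0))
  expect_length(intersect(c(g$cg$pos, g$cg$pos + 1L), g$ch$pos), 0)
})

test_that("planted DMR trajectories interpolate linearly between stages", {
  g <- small_genome()
  d <- make_design()
  t <- plant_truth(g, d, config = list(
    n_dmrs_per_tissue = 1, dmr_tissues = "forebrain", regain_fraction = 0,
    background_mcg = 0.8, dmr_low = 0.3, min_effect = 0.4,
    n_dmvs = 1, n_pmds = 1, pmd_widths = c(2e5, 2e5),
    n_mch_domains = 1, n_artefacts = 1, seed = 5))
  expect_equal(as.numeric(t$dmr_trajectories[1, ]),
               seq(0.8, 0.3, length.out = 4))
  # the hypo tissue follows the trajectory, other tissues stay at baseline
  dmr <- t$dmrs[1]
  centre <- floor((dmr$start + dmr$end) / 2)
  for (si in 1:4) {
    expect_equal(true_mcg_level(t, dmr$chrom, centre, "forebrain", si),
                 t$dmr_trajectories[1, si])
    expect_equal(true_mcg_level(t, dmr$chrom, centre, "heart", si), 0.8)
  }
})

test_that("planted DMVs and mCH domains define exact true levels", {
  g <- small_genome()
  d <- make_design()
  t <- small_truth(g, d)
  dmv <- t$dmvs[1]
  cg_in <- g$cg[chrom == dmv$chrom & pos > dmv$start & pos <= dmv$end]
  expect_gt(nrow(cg_in), 0)
  for (tis in unique(d$tissue))
    expect_true(all(true_mcg_level(t, cg_in$chrom, cg_in$pos, tis, 2) == 0.05))

  dom <- t$mch_domains[1]
  pos_in <- g$ch[chrom == dom$chrom & pos > dom$start & pos <= dom$end, pos][1]
  smp <- as.list(d[tissue == "heart" & stage == "P0" & replicate == 1])
  expect_equal(true_mch_level(t, dom$chrom, pos_in, smp),
               t$background_mch[["P0"]] * 2)
  ctrl <- as.list(d[is_control == TRUE][1])
  expect_equal(true_mch_level(t, dom$chrom, pos_in, ctrl), 0)
  # control samples carry zero mCH outside artefact regions
  lv_all <- true_mch_level(t, g$ch$chrom, g$ch$pos, ctrl)
  in_art <- !is.na(methsuite:::point_interval_index(g$ch$chrom, g$ch$pos,
                                                    t$artefacts))
  expect_true(all(lv_all[!in_art] == 0))
  expect_true(all(lv_all[in_art] == t$artefacts$level[1]))
})

test_that("planted effects below the configured minimum are rejected", {
  g <- small_genome()
  expect_error(
    plant_truth(g, make_design(), config = list(
      n_dmrs_per_tissue = 1, dmr_low = 0.6, min_effect = 0.4,
      background_mcg = 0.85, n_dmvs = 0, n_pmds = 0, n_mch_domains = 0,
      n_artefacts = 0, seed = 2)),
    "effect")
})

test_that("oversized feature requests fail with a clear error", {
  g <- generate_genome(c(chr1 = 3e5), seed = 2)
  expect_error(
    plant_truth(g, make_design(), config = list(
      n_pmds = 4, pmd_widths = c(2e5, 2e5), seed = 3)),
    "genome")
})

test_that("read counts follow the Poisson-Binomial noise model", {
  g <- generate_genome(c(chr1 = 2e5), seed = 21)
  d <- make_design()
  t <- small_truth(g, d, config = list(n_pmds = 0, pmd_widths = c(1e4, 1e4),
                                       n_mch_domains = 1, n_dmvs = 1,
                                       n_artefacts = 0,
                                       n_dmr_clusters_per_tissue = 0,
                                       mch_widths = c(2e4, 2e4)))
  smp <- as.list(d[1])
  sim <- simulate_counts(g, t, smp, seed = 3, n_lambda_sites = 40000)
  expect_true(all(sim$allc$mc <= sim$allc$cov))
  # lambda methylated fraction estimates the non-conversion rate
  frac <- sum(sim$lambda$mc) / sum(sim$lambda$cov)
  se <- sqrt(0.005 * 0.995 / sum(sim$lambda$cov))
  expect_lt(abs(frac - 0.005), 3 * se)
  # Poisson coverage mean
  expect_lt(abs(mean(sim$allc$cov) - 30), 0.5)
  # determinism
  sim2 <- simulate_counts(g, t, smp, seed = 3, n_lambda_sites = 40000)
  expect_identical(sim$allc, sim2$allc)
  sim3 <- simulate_counts(g, t, smp, seed = 4, n_lambda_sites = 40000)
  expect_false(identical(sim$allc, sim3$allc))
})

test_that("fully methylated sites with perfect conversion saturate counts", {
  g <- generate_genome(c(chr1 = 5e4), ch_density = 0, seed = 5)
  d <- make_design(nonconversion_rate = 0)
  t <- plant_truth(g, d, config = list(
    background_mcg = 1, site_sd = 0, site_range = c(1, 1), cgi_level = 1,
    n_dmrs_per_tissue = 0, n_dmr_clusters_per_tissue = 0,
    n_dmvs = 0, n_pmds = 0, n_mch_domains = 0,
    n_artefacts = 0, seed = 6))
  sim <- simulate_counts(g, t, as.list(d[1]), seed = 9)
  cg_rows <- sim$allc[substr(context, 1, 2) == "CG"]
  expect_true(all(cg_rows$mc == cg_rows$cov))
})

test_that("empirical methylated fraction converges to m + (1 - m) r", {
  g <- generate_genome(c(chr1 = 2e5), seed = 31)
  d <- make_design()
  t <- small_truth(g, d, config = list(n_dmrs_per_tissue = 0, n_dmvs = 0,
                                       n_dmr_clusters_per_tissue = 0,
                                       n_pmds = 0, n_mch_domains = 0,
                                       n_artefacts = 0, site_sd = 0,
                                       site_range = c(0.7, 0.7),
                                       background_mcg = 0.7, cgi_level = 0.7))
  sim <- simulate_counts(g, t, as.list(d[1]), seed = 12)
  cg_rows <- sim$allc[substr(context, 1, 2) == "CG"]
  expected <- 0.7 + 0.3 * 0.005
  frac <- sum(cg_rows$mc) / sum(cg_rows$cov)
  se <- sqrt(expected * (1 - expected) / sum(cg_rows$cov))
  expect_gt(sum(cg_rows$cov), 1e5)
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("truth manifests round-trip through JSON and BED", {
  g <- small_genome()
  t <- small_truth(g, make_design())
  path <- tempfile(fileext = ".json")
  write_manifest(t, path)
  t2 <- read_manifest(path)
  expect_equal(t2$dmrs$start, t$dmrs$start)
  expect_equal(t2$dmr_trajectories, unname(t$dmr_trajectories))
  expect_equal(t2$background_mch, t$background_mch)
  expect_equal(as.data.frame(t2$mch_domains[, .(chrom, start, end)]),
               as.data.frame(t$mch_domains[, .(chrom, start, end)]))
  bedp <- tempfile(fileext = ".bed")
  write_bed(truth_bed(t, "dmvs"), bedp)
  back <- read_bed(bedp)
  expect_equal(back$start, t$dmvs$start)
  expect_equal(back$end, t$dmvs$end)
})
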