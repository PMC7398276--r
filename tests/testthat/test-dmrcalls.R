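test_that("DMS calling flags strong between-sample differences only", {
  # identical counts across samples: zero statistic, no DMS
  mc <- matrix(5L, 20, 4); cov <- matrix(10L, 20, 4)
  res <- call_dms(mc, cov, rep("chr1", 20), seq_len(20) * 100L, n_perm = 50)
  expect_true(all(res$stat == 0))
  expect_false(any(res$is_dms))
  # one unmethylated sample among five methylated ones
  mc2 <- cbind(0L, matrix(30L, 50, 5))
  cov2 <- matrix(30L, 50, 6)
  mc2[2:50, 1] <- 30L                      # only site 1 differs
  res2 <- call_dms(mc2, cov2, rep("chr1", 50), seq_len(50) * 100L,
                   n_perm = 1000, seed = 2)
  expect_true(res2$is_dms[1])
  expect_equal(res2$hypo[[1]], 1L)
  expect_false(any(res2$is_dms[-1]))
  expect_error(call_dms(mc[, 1, drop = FALSE], cov[, 1, drop = FALSE],
                        "chr1", 1L), "2 samples")
})

test_that("null sites stay FDR-controlled in DMS calling", {
  set.seed(5)
  n <- 5000; S <- 6
  cov <- matrix(rpois(n * S, 30), n, S)
  mc <- matrix(rbinom(n * S, as.vector(cov), 0.8), n, S)
  res <- call_dms(mc, cov, rep("chr1", n), seq_len(n) * 50L,
                  n_perm = 50, seed = 6)
  expect_lte(sum(res$is_dms), 0.001 * n)
})

test_that("DMS merging honours distance and pattern compatibility", {
  mk <- function(pos, hypo) data.table(
    chrom = "chr1", pos = pos, stat = 10, p = 1e-6, p_adj = 1e-5,
    is_dms = TRUE, hypo = hypo)
  # three compatible DMSs within 250 bp merge into one CG-DMR
  d <- mk(c(100L, 200L, 300L), list(1L, 1L, c(1L, 2L)))
  out <- merge_dms_to_dmrs(d)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_dms, 3L)
  expect_equal(out$start, 99)
  expect_equal(out$end, 301)
  # two DMSs are never enough
  expect_equal(nrow(merge_dms_to_dmrs(mk(c(100L, 200L), list(1L, 1L)))), 0)
  # 251 bp apart never merges
  d2 <- mk(c(100L, 351L, 602L), list(1L, 1L, 1L))
  expect_equal(nrow(merge_dms_to_dmrs(d2)), 0)
  # 250 bp apart does
  d3 <- mk(c(100L, 350L, 600L), list(1L, 1L, 1L))
  expect_equal(nrow(merge_dms_to_dmrs(d3)), 1)
  # disjoint hypo-sample sets block the merge
  d4 <- mk(c(100L, 200L, 300L), list(1L, 2L, 2L))
  expect_equal(nrow(merge_dms_to_dmrs(d4)), 0)
})

test_that("bulk baseline matches the worked example and handles ties", {
  b <- baseline_bulk(c(0.10, 0.80, 0.82, 0.84))
  expect_equal(b$a, 1L)
  expect_equal(b$b, 0.81)
  expect_equal(b$hypo, 1L)
  expect_equal(b$window_range, 0.02)
  b2 <- baseline_bulk(rep(0.7, 6))
  expect_equal(b2$b, 0.7)
  expect_length(b2$hypo, 0)
  expect_error(baseline_bulk(c(0.5, NA)), "missing")
})

test_that("bulk baseline equals the exhaustive-window oracle", {
  set.seed(7)
  for (i in 1:200) {
    N <- sample(2:12, 1)
    x <- round(runif(N), 3)
    got <- baseline_bulk(x)
    ref <- baseline_oracle(x)
    expect_equal(got$a, ref$a)
    expect_equal(got$b, ref$b)
    expect_equal(got$hypo, ref$hypo)
  }
})

test_that("effect size is the gap from the most hypomethylated sample", {
  x <- c(0.10, 0.80, 0.82, 0.84)
  expect_equal(effect_size(x), 0.71)
  expect_equal(effect_size(rep(0.5, 5)), 0)
  set.seed(1)
  perm <- sample(x)
  expect_equal(effect_size(perm), effect_size(x))
})

test_that("loss/gain events follow the 0.1 threshold per stage interval", {
  ev <- count_mcg_events(c(0.8, 0.65, 0.60, 0.75))
  expect_equal(ev$loss, c(TRUE, FALSE, FALSE))
  expect_equal(ev$gain, c(FALSE, FALSE, TRUE))
  # the canonical single-loss case: 0.8 at one stage, 0.7 at the next
  ev2 <- count_mcg_events(c(0.8, 0.7))
  expect_equal(sum(ev2$loss), 1)
  expect_equal(sum(ev2$gain), 0)
  # monotone decline of >= 0.1 per step: k - 1 losses, no gains
  ev3 <- count_mcg_events(seq(0.9, 0.3, by = -0.15))
  expect_equal(sum(ev3$loss), 4)
  expect_equal(sum(ev3$gain), 0)
  expect_equal(nrow(count_mcg_events(0.5)), 0)
})

test_that("reversing a trajectory swaps loss and gain totals", {
  set.seed(11)
  for (i in 1:50) {
    traj <- runif(sample(3:8, 1))
    a <- count_mcg_events(traj)
    b <- count_mcg_events(rev(traj))
    expect_equal(sum(a$loss), sum(b$gain))
    expect_equal(sum(a$gain), sum(b$loss))
    expect_lte(sum(a$loss) + sum(a$gain), nrow(a))
  }
})

test_that("CG-DMR categories follow the fixed priority order", {
  promoters <- bed("chr1", c(1000, 20000), c(6000, 25000))
  cgis <- bed("chr1", c(2000, 40000), c(3000, 41000))
  shores <- bed("chr1", 41000, 43000)
  te <- bed("chr1", 90000, 91000)
  dmrs <- bed("chr1",
              start = c(2500, 21000, 40100, 41500, 60000, 60900, 70000, 90500, 95000),
              end   = c(2600, 21200, 40200, 41600, 60200, 61000, 70200, 90600, 95100))
  scores <- c(NA, NA, NA, NA, 0.31, NA, NA, NA, NA)
  effects <- c(0.5, 0.5, NA, NA, NA, NA, 0.4, 0.1, 0.05)
  got <- categorize_dmrs(dmrs, promoters, cgis, shores, te,
                         enhancer_scores = scores, effects = effects)
  expect_equal(as.character(got),
               c("CGI-promoter",           # promoter + CGI beats all
                 "non-CGI-promoter",
                 "CGI", "CGI-shore",
                 "distal-feDMR",           # 0.31 > 0.3, strict boundary
                 "flanking-distal-feDMR",  # within 1 kb of the feDMR
                 "primed-distal-feDMR",    # tissue-specific, effect 0.4
                 "te-unxDMR", "nte-unxDMR"))
  # partition: every DMR gets exactly one category
  expect_false(anyNA(got))
  expect_equal(sum(table(got)), nrow(dmrs))
  # score exactly at the cutoff is not an feDMR
  got2 <- categorize_dmrs(dmrs[5], promoters, cgis, shores, te,
                          enhancer_scores = 0.3, effects = NA_real_)
  expect_equal(as.character(got2), "nte-unxDMR")
  expect_warning(
    categorize_dmrs(dmrs[5], promoters, cgis, shores, te,
                    enhancer_scores = NULL, effects = NA_real_),
    "skipped")
})

test_that("mCG/H3K27ac association bins match the printed boundaries", {
  tab <- mcg_h3k27ac_association(c(0.65, 0.2, 0.4, 0.61), c(7.1, 2.0, -1, 6))
  expect_equal(unname(tab["H", "(6,Inf)"]), 1L)
  expect_equal(unname(tab["L", "[0,2]"]), 1L)   # 0.2 is L, 2.0 first column
  expect_equal(unname(tab["M", "[0,2]"]), 1L)   # negative ac -> first column
  expect_equal(unname(tab["H", "(4,6]"]), 1L)   # 6 falls in (4,6]
  expect_equal(sum(tab), 4L)
})

test_that("H3K27ac normalisation clamps, scales and keeps zero rows", {
  m <- rbind(c(-1, 2, 4), c(-3, -2, 0), c(0, 0, 5))
  nm <- normalize_h3k27ac(m)
  expect_equal(nm[1, ], c(0, 0.5, 1))
  expect_equal(nm[2, ], c(0, 0, 0))
  expect_equal(nm[3, ], c(0, 0, 1))
})

test_that("well-separated trajectory groups cluster perfectly", {
  set.seed(21)
  n <- 40
  truth <- rep(1:2, each = n / 2)
  mcg <- rbind(matrix(rep(c(0.8, 0.5, 0.2), each = n / 2), n / 2) ,
               matrix(rep(c(0.2, 0.5, 0.8), each = n / 2), n / 2))
  mcg <- mcg + rnorm(length(mcg), 0, 0.02)
  ac <- rbind(matrix(rep(c(0, 2, 6), each = n / 2), n / 2),
              matrix(rep(c(6, 2, 0), each = n / 2), n / 2))
  cl <- cluster_dmr_trajectories(mcg, ac, k = 2, seed = 3)
  expect_equal(ari(cl, truth), 1)
  expect_error(cluster_dmr_trajectories(mcg, ac, k = 100), "exceeds")
})
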