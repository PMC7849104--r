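test_that("exhaustive benchmark enumerates all subsets", {
  ranked <- c("a", "b", "c", "d")
  # hits occupy ranks {1, 2}: subset medians {1.5,2,2.5,2.5,3,3.5}
  r <- benchmark_rank_permutation(ranked, c("a", "b"))
  expect_equal(r$method, "exhaustive")
  expect_equal(sort(r$null_medians), c(1.5, 2, 2.5, 2.5, 3, 3.5))
  expect_equal(r$observed_median_rank, 1.5)
  expect_equal(r$p_one_tailed, 1 / 6)
  # hits = entire list -> p = 1
  full <- benchmark_rank_permutation(ranked, ranked, B = 50, seed = 2,
                                     method = "sampled")
  expect_equal(full$p_one_tailed, 1)
  expect_error(benchmark_rank_permutation(ranked, c("a", "zz")), "zz")
})

test_that("sampled benchmark is seeded, bounded and agrees with exhaustive", {
  ranked <- sprintf("s%03d", 1:100)
  r1 <- benchmark_rank_permutation(ranked, ranked[1:5], B = 999,
                                   seed = 7, method = "sampled")
  r2 <- benchmark_rank_permutation(ranked, ranked[1:5], B = 999,
                                   seed = 7, method = "sampled")
  expect_identical(r1$null_medians, r2$null_medians)
  expect_lte(r1$p_one_tailed, 0.01)          # hits at the very top
  expect_gte(r1$p_one_tailed, 1 / 1000)      # +1 correction floor
  # exhaustive and sampled agree within Monte-Carlo error
  small <- sprintf("t%02d", 1:15)
  ex <- benchmark_rank_permutation(small, small[c(2, 5, 9)],
                                   method = "exhaustive")
  sa <- benchmark_rank_permutation(small, small[c(2, 5, 9)], B = 4000,
                                   seed = 11, method = "sampled")
  expect_equal(sa$p_one_tailed, ex$p_one_tailed, tolerance = 0.05)
})

test_that("permutation p-values are calibrated under random hit sets", {
  set.seed(99)
  ranked <- sprintf("s%03d", 1:80)
  pvals <- vapply(1:200, function(s) {
    hits <- sample(ranked, 6)
    benchmark_rank_permutation(ranked, hits, B = 199, seed = s,
                               method = "sampled")$p_one_tailed
  }, numeric(1))
  expect_gte(mean(pvals <= 0.5), 0.4)
  expect_lte(mean(pvals <= 0.5), 0.6)
})

test_that("greedy pruning keeps best-scored representatives of LD clumps", {
  # A-B r2 high, B-C r2 high, A-C unlinked; scores A > B > C
  a <- c(0, 1, 2, 0, 1, 2, 0, 1)
  b <- c(0, 2, 2, 0, 1, 2, 0, 0)            # r2 with a ~ 0.71
  c_ <- c(0, 1, 1, 1, 2, 1, 2, 2)           # unlinked with both
  panel <- make_panel(list(a, b, c_), pos = c(1000L, 2000L, 3000L))
  stopifnot(ld_r2(panel, "rs1", "rs2") > 0.2,
            ld_r2(panel, "rs1", "rs3") < 0.2)
  rec <- data.frame(id = c("rs1", "rs2", "rs3"), lmi = c(3, 2, 1))
  kept <- prune_independent(rec, panel, r2_max = 0.2)
  expect_equal(kept$id, c("rs1", "rs3"))
  # unlinked records all survive; linked pair keeps the higher score
  rec2 <- data.frame(id = c("rs1", "rs2"), lmi = c(1, 5))
  expect_equal(prune_independent(rec2, panel)$id, "rs2")
  # post-condition: all pairwise r2 below the threshold within-window
  fx <- random_lmi_fixture(55)
  recs <- data.frame(id = names(fx$zmap), lmi = unname(fx$zmap))
  kept2 <- prune_independent(recs, fx$panel, r2_max = 0.2)
  v <- fx$panel$variants[match(kept2$id, fx$panel$variants$id), ]
  for (i in seq_len(nrow(kept2) - 1L)) for (j in (i + 1L):nrow(kept2)) {
    if (v$chrom[i] == v$chrom[j] &&
        abs(v$pos[i] - v$pos[j]) <= 500000) {
      r2 <- ld_r2(fx$panel, kept2$id[i], kept2$id[j])
      expect_true(is.na(r2) || r2 < 0.2)
    }
  }
})

test_that("rank-sum test reproduces exact enumeration and approximations agree", {
  r <- ranksum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_true(r$exact)
  expect_equal(r$p, 1 / 20)                   # 1 of C(6,3) labelings
  # identical samples, two-sided -> p = 1 by symmetry
  expect_equal(ranksum_test(c(1, 2, 9), c(2, 1, 9))$p, 1)
  # extreme configuration, one-sided "greater"
  rg <- ranksum_test(c(10, 11, 12, 13), c(1, 2, 3), "greater")
  expect_equal(rg$p, 1 / choose(7, 4))
  # exact and normal-approximation p agree on tie-free fixtures
  set.seed(4)
  for (i in 1:10) {
    x <- sample(100, 5); y <- sample(200:300, 6)
    ex <- ranksum_test(x, y)$p
    ap <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(ex - ap), 0.02)
  }
})

test_that("Spearman correlation works on mid-ranks", {
  expect_equal(spearman_cor(1:5, 2^(1:5)), 1)
  expect_equal(spearman_cor(1:5, -(1:5)), -1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_warning(r <- spearman_cor(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
})
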