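test_that("inverse-normal transform hits the quantile oracle and tie rule", {
  # n = 3 distinct ORs -> quantiles {1/6, 1/2, 5/6}
  z <- standardize_or(make_study(c(1.1, 1.2, 1.3)))
  expect_equal(unname(z), c(-0.9674216, 0, 0.9674216), tolerance = 1e-6)
  # n = 1 -> z = 0; ties get the mid-rank
  expect_equal(unname(standardize_or(make_study(1.5))), 0)
  expect_equal(unname(standardize_or(make_study(c(1.2, 1.2)))), c(0, 0))
  expect_length(standardize_or(make_study(1.1)[0, ]), 0)
  # strictly monotone in OR between distinct values
  set.seed(9)
  or <- 1 + sort(runif(50))
  z2 <- standardize_or(make_study(or))
  expect_true(all(diff(unname(z2)) > 0))
})

test_that("LMI arithmetic follows the LD-weighted local mean", {
  # perfect-LD neighborhood: equal weights -> plain average of z_j
  panel <- make_panel(list(c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1),
                           c(0, 1, 2, 0, 1)))
  z <- c(rs1 = 2, rs2 = 1, rs3 = 3)
  rec <- compute_lmi(z, panel)
  i <- match("rs1", rec$id)
  expect_equal(rec$local_mean[i], 2)          # (1 + 3) / 2
  expect_equal(rec$lmi[i], 4)                 # z_i * local mean
  expect_equal(rec$weight_sum[i], 2)
  # identity case: all neighbors share z -> LMI = z^2
  z_id <- c(rs1 = 1.5, rs2 = 1.5, rs3 = 1.5)
  rec_id <- compute_lmi(z_id, panel)
  expect_equal(rec_id$lmi, rep(2.25, 3))
  # no estimable neighbors -> estimable FALSE, lmi absent
  lone <- make_panel(list(c(0, 1, 2, 0)), pos = 1000L)
  rec_lone <- compute_lmi(c(rs1 = 1), lone)
  expect_false(rec_lone$estimable)
  expect_true(is.na(rec_lone$lmi))
})

test_that("windowed LMI equals the brute-force double loop on seeded fixtures", {
  for (seed in c(101, 202, 303)) {
    fx <- random_lmi_fixture(seed, n_blocks = 3, snps_per_block = 15)
    fast <- compute_lmi(fx$zmap, fx$panel)
    slow <- brute_lmi(fx$zmap, fx$panel)
    expect_equal(fast$estimable, slow$estimable)
    expect_lt(max(abs(fast$lmi - slow$lmi), na.rm = TRUE), 1e-10)
  }
})

test_that("LMI obeys the scale, bounds and weight-normalization laws", {
  fx <- random_lmi_fixture(77)
  rec <- compute_lmi(fx$zmap, fx$panel)
  est <- rec[rec$estimable, ]
  # scale: z -> c z multiplies LMI by c^2 exactly
  for (c0 in c(0.5, 3)) {
    rec_c <- compute_lmi(c0 * fx$zmap, fx$panel)
    expect_equal(rec_c$lmi, c0^2 * rec$lmi, tolerance = 1e-12)
  }
  # bounds: local mean is a convex combination of neighbor z values
  zr <- range(fx$zmap)
  expect_true(all(est$local_mean >= zr[1] - 1e-12 &
                  est$local_mean <= zr[2] + 1e-12))
  # SNPs below the panel-MAF floor or off panel are flagged not estimable
  z_extra <- c(fx$zmap, absent_snp = 1.0)
  rec_extra <- compute_lmi(z_extra, fx$panel)
  expect_false(rec_extra$estimable[rec_extra$id == "absent_snp"])
})

test_that("exclusion rules split negative-LMI and bottom-tail SNPs", {
  rec <- data.frame(
    id = c("a", "b", "c", "d"),
    z = c(-0.5, 1.0, 1.0, -1.5),
    lmi = c(0.2, -0.2, 0.5, NA),
    estimable = c(TRUE, TRUE, TRUE, FALSE))
  rec$local_mean <- rec$lmi / rec$z
  out <- filter_lmi(rec)
  # median z over all scored = 0.25: "a" has positive LMI but low z
  expect_true(out$excluded_bottom_tail[out$id == "a"])
  expect_false(out$excluded_negative[out$id == "a"])
  expect_true(out$excluded_negative[out$id == "b"])
  expect_true(out$retained[out$id == "c"])
  expect_true(is.na(out$retained[out$id == "d"]) ||
              !out$retained[out$id == "d"])
  # the two exclusion flags are never both set
  expect_false(any(out$excluded_negative & out$excluded_bottom_tail,
                   na.rm = TRUE))
  # boundary: z exactly at the median is retained
  rec2 <- data.frame(id = c("a", "b", "c"), z = c(1, 1, 2),
                     lmi = c(0.1, 0.2, 0.3),
                     estimable = TRUE)
  out2 <- filter_lmi(rec2)
  expect_true(all(out2$retained))
})

test_that("top-fraction selection uses floor and deterministic tie-breaks", {
  n <- 1000
  rec <- data.frame(id = sprintf("s%04d", 1:n), lmi = rev(seq_len(n)),
                    p = rep(0.5, n))
  sel <- select_top_fraction(rec, 0.005)
  expect_equal(sel$k, 5L)
  expect_equal(sel$selected$id, sprintf("s%04d", 1:5))
  expect_equal(sel$threshold, n - 4)
  # floor(0.005 * 200) = 1
  expect_equal(select_top_fraction(rec[1:200, ], 0.005)$k, 1L)
  # ties at the threshold break by smaller p then id
  tie <- data.frame(id = c("b", "a", "c"), lmi = c(5, 5, 5),
                    p = c(0.2, 0.2, 0.1))
  s2 <- select_top_fraction(tie, fraction = 2 / 3)
  expect_equal(s2$selected$id, c("c", "a"))
  expect_warning(select_top_fraction(rec[1:100, ], 0.005), "empty")
})
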