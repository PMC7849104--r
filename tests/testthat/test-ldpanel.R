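test_that("VCF loading keeps biallelic SNPs and records missingness", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  panel <- suppressMessages(load_genotypes(vcf))
  # rs3 (triallelic) and rs4 (indel) are skipped
  expect_equal(panel$variants$id, c("rs1", "rs2", "rs5"))
  expect_equal(attr(panel, "n_skipped"), 2L)
  expect_equal(unname(panel$dosage["rs1", ]), c(0, 1, 2, 1))
  # "./." is missing, not zero
  expect_equal(unname(panel$dosage["rs2", ]), c(0, NA, 1, 0))
  # phased separators parse like unphased
  expect_equal(unname(panel$dosage["rs5", ]), c(2, 1, 0, 1))
})

test_that("degenerate VCF inputs raise the contracted errors", {
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", "S1", sep = "\t"),
               paste("1", "100", "ins1", "A", "AT", ".", ".", ".",
                     "GT", "0/1", sep = "\t")), bad)
  expect_error(suppressWarnings(load_genotypes(bad)), "empty panel")
  expect_error(load_genotypes(withr::local_tempfile()), "not found")
})

test_that("panel construction enforces the sorting and uniqueness invariants", {
  v <- data.frame(id = c("a", "b"), chrom = "1", pos = c(200L, 100L),
                  ref = "A", alt = "G")
  p <- ld_panel(v, rbind(c(0, 1), c(1, 2)))   # sorts internally
  expect_equal(p$variants$id, c("b", "a"))
  expect_error(
    ld_panel(data.frame(id = c("a", "b"), chrom = "1", pos = 100L,
                        ref = "A", alt = "G"),
             rbind(c(0, 1), c(0, 1))),
    "duplicated")
  expect_error(
    ld_panel(data.frame(id = "a", chrom = "1", pos = 1L, ref = "A",
                        alt = "A"), rbind(c(0, 1))),
    "ref and alt")
})

test_that("allele frequencies match brute-force allele counting", {
  panel <- make_panel(list(c(0, 1, 1, 2), c(0, 0, 0, 0), c(2, 2, 2, 2),
                           c(0, NA, 1, NA)))
  expect_equal(allele_freq(panel, "rs1"), 0.5)     # 4 alt alleles / 8
  expect_equal(allele_freq(panel, "rs2"), 0)
  expect_equal(allele_freq(panel, "rs3"), 1)
  expect_equal(allele_freq(panel, "rs4"), 0.25)    # over non-missing only
  expect_equal(unname(panel_maf(panel)), c(0.5, 0, 0, 0.25))
  all_na <- make_panel(list(c(NA, NA)))
  expect_error(allele_freq(all_na, "rs1"), "missing")
})

test_that("HWE test agrees with hand chi-square arithmetic", {
  perfect <- make_panel(list(rep(c(0, 1, 2), c(25, 50, 25))))
  expect_equal(hwe_test(perfect, "rs1"), 1)
  het <- make_panel(list(rep(1, 100)))            # chi2 = 100 at 1 df
  expect_lt(hwe_test(het, "rs1"), 1e-6)
  expect_equal(hwe_test(het, "rs1"),
               pchisq(100, df = 1, lower.tail = FALSE))
  mono <- make_panel(list(rep(0, 100)))
  expect_equal(hwe_test(mono, "rs1"), 1)
  # brute-force agreement on a random 20-individual fixture
  set.seed(42)
  for (rep in 1:10) {
    d <- rbinom(20, 2, runif(1, 0.1, 0.9))
    pan <- make_panel(list(d))
    n <- length(d); f <- sum(d) / (2 * n)
    if (f %in% c(0, 1)) { expect_equal(hwe_test(pan, "rs1"), 1); next }
    ex <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    chi <- sum((c(sum(d == 0), sum(d == 1), sum(d == 2)) - ex)^2 / ex)
    expect_equal(hwe_test(pan, "rs1"),
                 pchisq(chi, 1, lower.tail = FALSE))
  }
})

test_that("r2 matches hand Pearson computation and its invariances", {
  panel <- make_panel(list(c(0, 1, 2, 0), c(0, 1, 1, 0), c(0, 0, 1, 1),
                           c(0, 1, 0, 1)))
  expect_equal(ld_r2(panel, "rs1", "rs2"), 2.25 / 2.75)
  expect_equal(ld_r2(panel, "rs3", "rs4"), 0)        # orthogonal
  expect_equal(ld_r2(panel, "rs1", "rs1"), 1)
  # symmetry and allele-flip invariance
  expect_identical(ld_r2(panel, "rs1", "rs2"), ld_r2(panel, "rs2", "rs1"))
  flipped <- make_panel(list(c(0, 1, 2, 0), 2 - c(0, 1, 1, 0)))
  expect_equal(ld_r2(flipped, "rs1", "rs2"), 2.25 / 2.75)
  # zero variance or too few complete pairs -> undefined
  degen <- make_panel(list(c(1, 1, 1, 1), c(0, 1, 2, 0),
                           c(0, NA, NA, NA)))
  expect_true(is.na(ld_r2(degen, "rs1", "rs2")))
  expect_true(is.na(ld_r2(degen, "rs3", "rs2")))
})

test_that("neighbor windows apply distance and MAF matching rules", {
  # focal rs1 at 1,000,000 with MAF 0.30
  panel <- make_panel(
    list(rep(c(0, 1, 2), c(6, 2, 2)),     # maf .3 focal
         rep(c(0, 1, 2), c(6, 2, 2)),     # maf .3, at boundary
         rep(c(0, 1), c(8, 2)),           # maf .1, in window
         rep(c(0, 1, 2), c(5, 4, 1)),     # maf .3, in window
         rep(c(0, 1, 2), c(6, 2, 2))),    # maf .3, outside window
    pos = c(1000000L, 1500000L, 900000L, 1100000L, 1500001L))
  got <- neighbors_window(panel, "rs1", 500000, 0.05)
  expect_equal(got, c("rs4", "rs2"))      # ordered by position
  # boundary is inclusive, MAF 0.10 vs 0.30 excluded at tol 0.05
  expect_true("rs2" %in% got)
  expect_false("rs3" %in% got)
  # tolerance 1 reduces to the pure distance window
  expect_equal(neighbors_window(panel, "rs1", 500000, 1),
               c("rs3", "rs4", "rs2"))
  # monotone: the neighbor set grows with the tolerance
  tols <- c(0.01, 0.05, 0.2, 1)
  sets <- lapply(tols, function(t) neighbors_window(panel, "rs1", 5e5, t))
  for (i in seq_len(length(sets) - 1L))
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
})
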