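# Shared fixture builders. Everything is generated in code; no binary
# data ships with the package.

# quick panel from a list of dosage vectors
make_panel <- function(dosages, pos = NULL, chrom = "1", ids = NULL) {
  m <- length(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- paste0("rs", seq_len(m))
  ld_panel(
    data.frame(id = ids, chrom = chrom, pos = as.integer(pos),
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    do.call(rbind, dosages))
}

# minimal study_set around given ORs
make_study <- function(or, ids = paste0("rs", seq_along(or)),
                       pos = seq_along(or) * 1000L, chrom = "1",
                       se = rep(0.1, length(or)),
                       p = rep(0.5, length(or)),
                       maf = rep(0.3, length(or))) {
  study_set(data.frame(
    id = ids, chrom = chrom, pos = pos,
    effect_allele = "G", other_allele = "A",
    or = or, se = se, p = p, maf = maf,
    stringsAsFactors = FALSE))
}

# independent brute-force Local Moran's Index oracle: double loop over
# all variant pairs using only the public primitives, same predicates
# as compute_lmi but none of its code path
brute_lmi <- function(zmap, panel, half_window_bp = 500000,
                      maf_tolerance = 0.05, min_panel_maf = 0.01) {
  v <- panel$variants
  maf <- panel_maf(panel)
  out <- data.frame(id = names(zmap), lmi = NA_real_,
                    estimable = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(zmap)) {
    i <- match(names(zmap)[k], v$id)
    if (is.na(i) || is.na(maf[i]) || maf[i] < min_panel_maf) next
    num <- 0; den <- 0
    for (j in seq_len(nrow(v))) {
      if (j == i) next
      if (v$chrom[j] != v$chrom[i]) next
      if (abs(v$pos[j] - v$pos[i]) > half_window_bp) next
      if (is.na(maf[j]) || abs(maf[j] - maf[i]) > maf_tolerance) next
      zj <- zmap[v$id[j]]
      if (is.na(zj)) next                       # neighbor not scored
      w <- ld_r2(panel, v$id[i], v$id[j])
      if (is.na(w)) next
      num <- num + unname(zj) * w
      den <- den + w
    }
    if (den > 0) {
      out$lmi[k] <- unname(zmap[k]) * num / den
      out$estimable[k] <- TRUE
    }
  }
  out
}

# a small seeded panel plus z-scores for oracle comparisons
random_lmi_fixture <- function(seed, n_blocks = 4, snps_per_block = 25,
                               n_ind = 60) {
  cfg <- sim_config(
    seed = seed, n_individuals = n_ind,
    blocks = replicate(n_blocks,
                       sim_block(snps_per_block, founders = 8L,
                                 mutation_rate = 0.02,
                                 maf_range = c(0.05, 0.5)),
                       simplify = FALSE),
    block_gap = 3e5)             # blocks overlap within the window
  panel <- simulate_panel(cfg)
  set.seed(seed + 1000L)
  ids <- panel$variants$id
  # score most SNPs; leave some unscored to exercise the restriction
  scored <- sort(sample(seq_along(ids), round(0.9 * length(ids))))
  list(panel = panel,
       zmap = stats::setNames(stats::rnorm(length(scored)), ids[scored]))
}

# plain-text VCF used by the loader tests: 3 biallelic SNPs (one with a
# missing genotype), 1 triallelic record, 1 indel
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
          "INFO", "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    paste("1", "1000", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/1", sep = "\t"),
    paste("1", "2000", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "./.", "0/1", "0/0", sep = "\t"),
    paste("1", "3000", "rs3", "G", "A,C", ".", "PASS", ".", "GT",
          "0/1", "0/2", "0/0", "1/2", sep = "\t"),
    paste("1", "4000", "rs4", "G", "GTT", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0/0", "0/0", sep = "\t"),
    paste("2", "1500", "rs5", "T", "C", ".", "PASS", ".", "GT",
          "1|1", "0|1", "0|0", "0|1", sep = "\t")), path)
  path
}
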