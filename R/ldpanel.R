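#' Construct an LD reference panel
#'
#' An `ld_panel` holds biallelic SNPs and their additive dosages across a
#' set of reference individuals. It backs all linkage-disequilibrium
#' queries: allele frequencies, Hardy-Weinberg tests, pairwise r², and
#' the distance + MAF-matched neighbor windows used by the Local Moran's
#' Index.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based
#'   bp), `ref`, `alt`. Must be strictly sorted by (`chrom`, `pos`) with
#'   no duplicated (`chrom`, `pos`, `ref`, `alt`) and no duplicated `id`.
#' @param dosage numeric matrix, one row per variant and one column per
#'   panel individual; entries in {0, 1, 2, NA} counting alt alleles.
#' @return An object of class `ld_panel`: a list with elements
#'   `variants`, `dosage`, and `n_individuals`.
#' @examples
#' v <- data.frame(id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'                 ref = "A", alt = "G")
#' d <- rbind(c(0, 1, 2, 1), c(0, 1, 1, 0))
#' p <- ld_panel(v, d)
#' allele_freq(p, "rs1")
#' @export
ld_panel <- function(variants, dosage) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(variants) == 0L) stop("empty panel: no variants")
  if (nrow(dosage) != nrow(variants))
    stop("dosage must have one row per variant")
  if (any(variants$pos < 1L)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt must differ")
  if (anyDuplicated(variants$id))
    stop("duplicated variant id: ",
         variants$id[duplicated(variants$id)][1L])
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key))
    stop("duplicated (chrom, pos, ref, alt) record: ",
         key[duplicated(key)][1L])
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
  }
  # strict sort: within a chromosome positions must not repeat
  if (anyDuplicated(paste(variants$chrom, variants$pos)))
    stop("variants must be strictly sorted: duplicated (chrom, pos)")
  bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
  if (length(bad)) stop("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- variants$id
  rownames(variants) <- NULL
  structure(list(variants = variants, dosage = dosage,
                 n_individuals = ncol(dosage)),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d variants x %d individuals, %d chromosome(s)\n",
              nrow(x$variants), x$n_individuals,
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Load a reference panel from a VCF file
#'
#' Reads genotypes (GT field) from a plain or bgzipped VCF and retains
#' biallelic SNP records only; multiallelic and non-SNP (indel) records
#' are skipped and counted. Missing genotypes become `NA` dosages.
#'
#' @param vcf_source path to a VCF file with GT genotype fields.
#' @return An [ld_panel()]; the number of skipped non-biallelic-SNP
#'   records is available as `attr(panel, "n_skipped")`.
#' @export
load_genotypes <- function(vcf_source) {
  if (!file.exists(vcf_source)) stop("VCF not found: ", vcf_source)
  v <- tryCatch(vcfR::read.vcfR(vcf_source, verbose = FALSE),
                error = function(e)
                  stop("malformed VCF '", vcf_source, "': ",
                       conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_total <- nrow(fix)
  if (n_total == 0L) stop("empty panel: VCF '", vcf_source,
                          "' has no variant records")
  base <- c("A", "C", "G", "T")
  keep <- fix$REF %in% base & fix$ALT %in% base   # single-base, no comma
  n_skipped <- sum(!keep)
  if (!any(keep))
    stop("empty panel: no biallelic SNP records retained from '",
         vcf_source, "'")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS, "_", fix$REF, "/", fix$ALT),
                fix$ID)
  dosage <- .gt_to_dosage(gt)
  panel <- ld_panel(
    data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    dosage)
  attr(panel, "n_skipped") <- n_skipped
  if (n_skipped > 0L)
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  panel
}

# "0/1", "1|1", "./." etc. -> alt-allele count or NA
.gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1L]]
    if (any(al == ".") || !length(al)) return(NA_real_)
    sum(al == "1")
  }, numeric(1))
  out <- matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt))
  rownames(out) <- rownames(gt)
  out
}

.panel_index <- function(panel, variant_id) {
  i <- match(variant_id, panel$variants$id)
  if (anyNA(i)) stop("variant not in panel: ",
                     paste(variant_id[is.na(i)], collapse = ", "))
  i
}

#' Alt-allele frequency of a panel variant
#'
#' Frequency of the alt allele over non-missing dosages. The minor
#' allele frequency is `min(f, 1 - f)`; see [panel_maf()] for the
#' vectorized MAF view.
#'
#' @param panel an [ld_panel()].
#' @param variant_id variant id present in the panel.
#' @return Alt-allele frequency in \[0, 1\].
#' @export
allele_freq <- function(panel, variant_id) {
  d <- panel$dosage[.panel_index(panel, variant_id), ]
  d <- d[!is.na(d)]
  if (!length(d)) stop("undefined frequency: all dosages missing for ",
                       variant_id)
  sum(d) / (2 * length(d))
}

#' Minor allele frequencies for panel variants
#'
#' @param panel an [ld_panel()].
#' @param ids variant ids; defaults to every panel variant.
#' @return Named numeric vector of MAFs; `NA` where all dosages are
#'   missing.
#' @export
panel_maf <- function(panel, ids = NULL) {
  idx <- if (is.null(ids)) seq_len(nrow(panel$variants)) else
    .panel_index(panel, ids)
  f <- rowMeans(panel$dosage[idx, , drop = FALSE], na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  stats::setNames(pmin(f, 1 - f), panel$variants$id[idx])
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the observed
#' (hom-ref, het, hom-alt) counts against Hardy-Weinberg expectations
#' computed from the estimated allele frequency. Monomorphic variants
#' return p = 1 by convention.
#'
#' @inheritParams allele_freq
#' @return Two-sided chi-square p-value.
#' @export
hwe_test <- function(panel, variant_id) {
  d <- panel$dosage[.panel_index(panel, variant_id), ]
  d <- d[!is.na(d)]
  if (!length(d)) stop("no non-missing genotypes for ", variant_id)
  n <- length(d)
  obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  f <- sum(d) / (2 * n)
  if (f == 0 || f == 1) return(1)
  expd <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  chisq <- sum((obs - expd)^2 / expd)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two variants' dosage vectors over
#' individuals non-missing in both. Undefined LD (fewer than two
#' complete individuals, or zero dosage variance in either variant)
#' returns `NA`; callers treat such weights as absent.
#'
#' @param panel an [ld_panel()].
#' @param id_a,id_b variant ids present in the panel.
#' @return r² in \[0, 1\], or `NA_real_` when undefined.
#' @export
ld_r2 <- function(panel, id_a, id_b) {
  a <- panel$dosage[.panel_index(panel, id_a), ]
  b <- panel$dosage[.panel_index(panel, id_b), ]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

# r2 of one focal variant against a block of panel rows. Uses the same
# scalar arithmetic as ld_r2 so boundary cases (exact zero correlation,
# zero variance) agree bit-for-bit with the pairwise primitive.
.r2_vec <- function(x, Y) {
  if (nrow(Y) == 0L) return(numeric(0))
  apply(Y, 1L, function(y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) return(NA_real_)
    a <- x[ok]; b <- y[ok]
    if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
    stats::cor(a, b)^2
  })
}

#' Distance and MAF-matched neighbor window
#'
#' All other panel variants on the focal variant's chromosome within
#' `half_window_bp` (boundary inclusive) whose panel MAF differs from
#' the focal MAF by at most `maf_tolerance`. This is the neighborhood
#' definition used by [compute_lmi()]: physical distance bounds the
#' window and MAF matching maximizes the chance that haplotypes match.
#'
#' @inheritParams allele_freq
#' @param half_window_bp half window width in bp (default 500 kb).
#' @param maf_tolerance maximum absolute MAF difference (default 0.05);
#'   1 disables MAF matching.
#' @return Character vector of neighbor ids ordered by position (may be
#'   empty).
#' @export
neighbors_window <- function(panel, variant_id, half_window_bp = 500000,
                             maf_tolerance = 0.05) {
  stopifnot(half_window_bp > 0, maf_tolerance >= 0)
  i <- .panel_index(panel, variant_id)
  v <- panel$variants
  same <- which(v$chrom == v$chrom[i] &
                abs(v$pos - v$pos[i]) <= half_window_bp)
  same <- setdiff(same, i)
  if (!length(same)) return(character(0))
  maf <- panel_maf(panel, c(variant_id, v$id[same]))
  keep <- !is.na(maf[-1L]) & !is.na(maf[1L]) &
    abs(maf[-1L] - maf[1L]) <= maf_tolerance
  v$id[same][keep]
}
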