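#' Read chromatin interaction calls from a BEDPE-like file
#'
#' Parses a tab-separated file whose first seven columns are
#' `chrom1, start1, end1, chrom2, start2, end2, p` (BEDPE convention:
#' 0-based, half-open bins). Both bins of a pair must have width
#' `bin_size`; trans (inter-chromosomal) pairs are skipped with a
#' count.
#'
#' @param bedpe_source path to the file.
#' @param bin_size expected bin width in bp (default 40000, i.e. 40-kb
#'   resolution interaction matrices).
#' @param header whether the file has a header row (default FALSE).
#' @return A data.frame of class `interaction_pairs` with columns
#'   `chrom`, `start_a`, `end_a`, `start_b`, `end_b`, `p` and an
#'   `n_trans_skipped` attribute.
#' @export
read_interactions <- function(bedpe_source, bin_size = 40000,
                              header = FALSE) {
  raw <- utils::read.delim(bedpe_source, header = header,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 7L)
    stop("expected >= 7 columns (chrom1,start1,end1,chrom2,start2,end2,p) in '",
         bedpe_source, "'")
  x <- raw[, 1:7]
  names(x) <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                "end_b", "p")
  for (f in c("start_a", "end_a", "start_b", "end_b", "p"))
    x[[f]] <- suppressWarnings(as.numeric(x[[f]]))
  bad <- which(!stats::complete.cases(x) |
               x$start_a >= x$end_a | x$start_b >= x$end_b |
               x$p < 0 | x$p > 1)
  if (length(bad))
    stop("malformed interaction row ", bad[1L], " in '", bedpe_source, "'")
  w <- which(x$end_a - x$start_a != bin_size |
             x$end_b - x$start_b != bin_size)
  if (length(w))
    stop("row ", w[1L], ": bin width differs from bin_size = ", bin_size)
  trans <- x$chrom_a != x$chrom_b
  out <- x[!trans, , drop = FALSE]
  out <- data.frame(chrom = as.character(out$chrom_a),
                    start_a = out$start_a, end_a = out$end_a,
                    start_b = out$start_b, end_b = out$end_b,
                    p = out$p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("interaction_pairs", "data.frame")
  attr(out, "n_trans_skipped") <- sum(trans)
  attr(out, "bin_size") <- bin_size
  out
}

#' Bonferroni filter for interaction calls
#'
#' Adjusts each interaction p-value for `m` tests
#' (`adjusted_p = min(1, p * m)`) and retains pairs whose adjusted
#' p-value is below `alpha`. Multiplying p by m and comparing to alpha
#' is algebraically identical to comparing raw p against `alpha / m`.
#'
#' @param pairs an `interaction_pairs` data.frame (see
#'   [read_interactions()]).
#' @param m number of tests (defaults to `nrow(pairs)`; must be at
#'   least that).
#' @param alpha significance threshold on the adjusted p (default
#'   1e-5, strict).
#' @return The retained pairs with an `adjusted_p` column.
#' @export
bonferroni_filter <- function(pairs, m = nrow(pairs), alpha = 1e-5) {
  stopifnot(is.data.frame(pairs), "p" %in% names(pairs),
            m >= nrow(pairs))
  pairs$adjusted_p <- pmin(1, pairs$p * m)
  out <- pairs[pairs$adjusted_p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_pairs", "data.frame")
  out
}

#' Retain the top fraction of interactions matched to a reference set
#'
#' When one dataset has been filtered to `reference_kept` of
#' `reference_total` interactions, keeps the same fraction of another
#' dataset by p-value: the `floor(fraction * n)` smallest-p pairs.
#'
#' @param reference_total,reference_kept counts defining the retained
#'   fraction in the reference dataset.
#' @param other_pairs an `interaction_pairs` data.frame to subset.
#' @return The retained pairs (smallest p first); the applied fraction
#'   is in `attr(x, "fraction")`. Keeps zero pairs, with a warning, when
#'   the floor is zero.
#' @export
match_top_fraction <- function(reference_total, reference_kept,
                               other_pairs) {
  stopifnot(reference_kept > 0, reference_kept <= reference_total,
            is.data.frame(other_pairs), "p" %in% names(other_pairs))
  fraction <- reference_kept / reference_total
  k <- floor(fraction * nrow(other_pairs))
  if (k == 0L && nrow(other_pairs) > 0L)
    warning("floor(fraction * n) = 0: no interactions retained")
  ord <- order(other_pairs$p)
  out <- other_pairs[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_pairs", "data.frame")
  attr(out, "fraction") <- fraction
  out
}

#' Overlap prioritized SNPs with interaction bins
#'
#' A SNP overlaps an interaction pair when its position falls inside
#' either bin under the half-open `[start, end)` convention; the bin
#' containing the SNP is reported as the bait and the partner bin as
#' the target. One annotation row is produced per (SNP, pair)
#' combination, so a SNP can bait several interactions.
#'
#' @param snps data.frame with columns `id`, `chrom`, `pos`.
#' @param pairs an `interaction_pairs` data.frame (typically after
#'   [bonferroni_filter()]).
#' @return A data.frame of class `overlap_annotations`: `snp_id`,
#'   `chrom`, `pos`, `pair_index`, `bait_start`, `bait_end`,
#'   `target_start`, `target_end`, `p`.
#' @export
overlap_snps <- function(snps, pairs) {
  stopifnot(is.data.frame(snps),
            all(c("id", "chrom", "pos") %in% names(snps)),
            is.data.frame(pairs))
  rows <- list()
  for (j in seq_len(nrow(pairs))) {
    same <- snps$chrom == pairs$chrom[j]
    in_a <- same & snps$pos >= pairs$start_a[j] &
      snps$pos < pairs$end_a[j]
    in_b <- same & snps$pos >= pairs$start_b[j] &
      snps$pos < pairs$end_b[j]
    for (side in c("a", "b")) {
      hit <- if (side == "a") in_a else in_b
      if (!any(hit)) next
      bait <- if (side == "a") c(pairs$start_a[j], pairs$end_a[j]) else
        c(pairs$start_b[j], pairs$end_b[j])
      targ <- if (side == "a") c(pairs$start_b[j], pairs$end_b[j]) else
        c(pairs$start_a[j], pairs$end_a[j])
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snps$id[hit], chrom = snps$chrom[hit],
        pos = snps$pos[hit], pair_index = j,
        bait_start = bait[1L], bait_end = bait[2L],
        target_start = targ[1L], target_end = targ[2L],
        p = pairs$p[j], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), chrom = character(0),
               pos = numeric(0), pair_index = integer(0),
               bait_start = numeric(0), bait_end = numeric(0),
               target_start = numeric(0), target_end = numeric(0),
               p = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("overlap_annotations", "data.frame")
  out
}

#' Annotate target bins with overlapping genes
#'
#' Adds to each bait/target annotation the names of genes whose
#' interval shares at least one base with the target bin (both
#' intervals taken 0-based, half-open as in BED).
#'
#' @param annotations an `overlap_annotations` data.frame from
#'   [overlap_snps()].
#' @param gene_bed path to a BED file (`chrom`, `start`, `end`, `name`)
#'   or an equivalently named data.frame.
#' @return `annotations` with a list-column `target_genes` (gene names
#'   sorted by gene start; possibly empty character vectors).
#' @export
annotate_targets <- function(annotations, gene_bed) {
  genes <- if (is.character(gene_bed)) {
    g <- utils::read.delim(gene_bed, header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(g) < 4L) stop("BED needs >= 4 columns (chrom,start,end,name)")
    g <- g[, 1:4]
    names(g) <- c("chrom", "start", "end", "name")
    g
  } else as.data.frame(gene_bed)
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)))
  genes$start <- suppressWarnings(as.numeric(genes$start))
  genes$end <- suppressWarnings(as.numeric(genes$end))
  bad <- which(!is.finite(genes$start) | !is.finite(genes$end) |
               genes$start >= genes$end)
  if (length(bad)) stop("malformed gene interval at BED row ", bad[1L])
  annotations$target_genes <- lapply(seq_len(nrow(annotations)),
    function(i) {
      hit <- genes$chrom == annotations$chrom[i] &
        genes$start < annotations$target_end[i] &
        genes$end > annotations$target_start[i]
      g <- genes[hit, , drop = FALSE]
      g$name[order(g$start)]
    })
  annotations
}
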