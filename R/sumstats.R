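#' Construct a set of GWAS summary statistics
#'
#' A `study_set` is a data.frame of per-SNP association summaries with
#' columns `id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `or`,
#' `beta`, `se`, `p`, `maf`, `info`, `flipped`. `beta = log(or)` is the
#' canonical effect scale; the odds ratio is the derived view.
#'
#' @param records data.frame with at least `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `se`, `p`, `maf` and one (or both,
#'   if consistent) of `or` / `beta`. Optional: `info`, `flipped`.
#' @param provenance free-text label describing the study.
#' @return A `study_set` data.frame sorted by (`chrom`, `pos`) with
#'   unique ids.
#' @export
study_set <- function(records, provenance = "") {
  req <- c("id", "chrom", "pos", "effect_allele", "other_allele",
           "se", "p", "maf")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  has_or <- "or" %in% names(records)
  has_beta <- "beta" %in% names(records)
  if (!has_or && !has_beta) stop("one of 'or' or 'beta' is required")
  x <- data.frame(id = as.character(records$id),
                  chrom = as.character(records$chrom),
                  pos = as.integer(records$pos),
                  effect_allele = as.character(records$effect_allele),
                  other_allele = as.character(records$other_allele),
                  or = if (has_or) as.numeric(records$or) else
                    exp(as.numeric(records$beta)),
                  beta = if (has_beta) as.numeric(records$beta) else
                    log(as.numeric(records$or)),
                  se = as.numeric(records$se),
                  p = as.numeric(records$p),
                  maf = as.numeric(records$maf),
                  info = if ("info" %in% names(records))
                    as.numeric(records$info) else
                      rep(NA_real_, nrow(records)),
                  flipped = if ("flipped" %in% names(records))
                    as.logical(records$flipped) else
                      rep(FALSE, nrow(records)),
                  stringsAsFactors = FALSE)
  if (has_or && has_beta &&
      any(abs(x$beta - log(x$or)) > 1e-9, na.rm = TRUE))
    stop("inconsistent 'or' and 'beta' (beta must equal log(or))")
  if (anyDuplicated(x$id))
    stop("duplicated SNP id: ", x$id[duplicated(x$id)][1L])
  if (any(x$se <= 0, na.rm = TRUE)) stop("se must be positive")
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("study_set", "data.frame")
  attr(x, "provenance") <- provenance
  x
}

#' Read GWAS summary statistics from a TSV file
#'
#' Parses a tab-separated file with a header row. Rows with non-numeric
#' or non-positive OR/SE, or p outside (0, 1], are rejected with
#' row-numbered diagnostics (available as `attr(x, "rejected")`);
#' duplicated ids are a hard error.
#'
#' @param tsv_source path to the TSV file.
#' @param column_map named character vector mapping internal field names
#'   (`id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `or` or
#'   `beta`, `se`, `p`, `maf`, optionally `info`) to column names in the
#'   file. Fields absent from the map are looked up under their own
#'   names.
#' @param provenance free-text label stored on the result.
#' @return A [study_set()].
#' @export
read_summary_stats <- function(tsv_source, column_map = character(),
                               provenance = tsv_source) {
  raw <- utils::read.delim(tsv_source, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  fields <- c("id", "chrom", "pos", "effect_allele", "other_allele",
              "or", "beta", "se", "p", "maf", "info", "flipped")
  cols <- stats::setNames(fields, fields)
  cols[names(column_map)] <- column_map
  present <- fields[cols[fields] %in% names(raw)]
  req <- c("id", "chrom", "pos", "effect_allele", "other_allele",
           "se", "p", "maf")
  miss <- setdiff(req, present)
  if (length(miss))
    stop("required column(s) not found in '", tsv_source, "': ",
         paste(cols[miss], collapse = ", "))
  if (!any(c("or", "beta") %in% present))
    stop("neither an 'or' nor a 'beta' column found in '", tsv_source, "'")
  x <- raw[, cols[present], drop = FALSE]
  names(x) <- present
  num <- intersect(c("pos", "or", "beta", "se", "p", "maf", "info"),
                   present)
  for (f in num) x[[f]] <- suppressWarnings(as.numeric(x[[f]]))
  if ("flipped" %in% present) x$flipped <- as.logical(x$flipped)
  eff <- if ("or" %in% present) x$or else exp(x$beta)
  bad <- !is.finite(x$se) | x$se <= 0 |
    !is.finite(x$p) | x$p <= 0 | x$p > 1 |
    !is.finite(x$maf) | x$maf <= 0 | x$maf > 0.5 |
    !is.finite(eff) | eff <= 0
  if (any(bad)) {
    rejected <- data.frame(row = which(bad),
                           id = as.character(x$id[bad]))
    message(sum(bad), " row(s) rejected during summary-stat parsing")
    x <- x[!bad, , drop = FALSE]
  } else rejected <- data.frame(row = integer(0), id = character(0))
  if (!nrow(x)) stop("no valid rows in '", tsv_source, "'")
  out <- study_set(x, provenance = provenance)
  attr(out, "rejected") <- rejected
  out
}

#' Write summary statistics to a TSV file
#'
#' Inverse of [read_summary_stats()] for the canonical column layout;
#' retained fields round-trip exactly.
#'
#' @param study a [study_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(study, path) {
  utils::write.table(as.data.frame(study), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Refer every record to the risk-increasing allele
#'
#' Records with OR < 1 have effect and other alleles swapped, the OR
#' replaced by its reciprocal and beta negated, so that every record has
#' OR >= 1; `p`, `se` and `maf` are untouched and the `flipped` flag
#' records the swap. OR exactly 1 is kept unflipped. Records with a
#' non-positive OR are dropped. Idempotent.
#'
#' @param study a [study_set()].
#' @return The harmonized [study_set()].
#' @export
harmonize_to_risk_allele <- function(study) {
  stopifnot(inherits(study, "study_set"))
  bad <- !is.finite(study$or) | study$or <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) with non-positive OR dropped")
    study <- study[!bad, , drop = FALSE]
  }
  flip <- study$or < 1
  ea <- study$effect_allele
  study$effect_allele[flip] <- study$other_allele[flip]
  study$other_allele[flip] <- ea[flip]
  study$or[flip] <- 1 / study$or[flip]
  study$beta[flip] <- -study$beta[flip]
  study$flipped <- study$flipped | flip
  class(study) <- c("study_set", "data.frame")
  study
}

#' Filter summary statistics on MAF and imputation quality
#'
#' Retains records with `maf > min_maf` (strict, so a record at exactly
#' the threshold is removed) and with `info` either absent or
#' `>= min_info`.
#'
#' @param study a [study_set()].
#' @param min_maf minor-allele-frequency threshold (default 0.05).
#' @param min_info minimum imputation info score (default 0.91).
#' @return The filtered [study_set()]; counts removed per criterion are
#'   in `attr(x, "qc_report")` (a row can count toward both).
#' @export
qc_filter <- function(study, min_maf = 0.05, min_info = 0.91) {
  stopifnot(inherits(study, "study_set"),
            min_maf >= 0, min_maf <= 1, min_info >= 0, min_info <= 1)
  fail_maf <- !(study$maf > min_maf)
  fail_info <- !is.na(study$info) & study$info < min_info
  out <- study[!(fail_maf | fail_info), , drop = FALSE]
  class(out) <- c("study_set", "data.frame")
  attr(out, "qc_report") <- c(maf = sum(fail_maf), info = sum(fail_info))
  out
}
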