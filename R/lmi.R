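#' Rank-based inverse-normal transform of odds ratios
#'
#' Standardizes the ORs of a harmonized study (all OR >= 1) by mapping
#' them through the inverse of the normal distribution: mid-ranks over
#' ascending OR, offset quantiles `q = (rank - 0.5) / n`, and
#' `z = qnorm(q)`. The transform is strictly monotone between distinct
#' OR values, so median splits on z and on OR coincide.
#'
#' @param study a harmonized [study_set()] (see
#'   [harmonize_to_risk_allele()]).
#' @return Named numeric vector of z scores keyed by SNP id (empty for
#'   an empty study).
#' @export
standardize_or <- function(study) {
  stopifnot(inherits(study, "study_set"))
  if (!nrow(study)) return(stats::setNames(numeric(0), character(0)))
  if (any(study$or < 1))
    warning("study does not look harmonized: OR < 1 present")
  r <- rank(study$or, ties.method = "average")
  z <- stats::qnorm((r - 0.5) / nrow(study))
  stats::setNames(z, study$id)
}

#' Genomic Local Moran's Index per SNP
#'
#' For each scored SNP i, the statistic is
#' `LMI_i = z_i * sum_j(z_j * r2_ij) / sum_j(r2_ij)`, where the sum runs
#' over the scored SNPs within `half_window_bp` on the same chromosome
#' whose panel MAF matches the focal MAF within `maf_tolerance`, and
#' `r2_ij` is panel LD. A large positive LMI marks a SNP whose elevated
#' standardized OR is shared by its LD neighborhood — the "hot spots"
#' the method prioritizes.
#'
#' SNPs absent from the panel, with panel MAF < `min_panel_maf`, or with
#' no usable neighbor weight are reported with `estimable = FALSE`
#' rather than dropped.
#'
#' @param zmap named numeric vector of z scores from [standardize_or()].
#' @param panel an [ld_panel()] providing positions, MAFs and LD.
#' @param half_window_bp half window in bp (default 500 kb, boundary
#'   inclusive).
#' @param maf_tolerance absolute MAF-matching tolerance (default 0.05).
#' @param min_panel_maf panel MAF below which a focal SNP is declared
#'   not estimable (default 0.01).
#' @return A data.frame of class `lmi_records`: `id`, `z`,
#'   `n_neighbors`, `weight_sum`, `local_mean`, `lmi`, `estimable`.
#' @export
compute_lmi <- function(zmap, panel, half_window_bp = 500000,
                        maf_tolerance = 0.05, min_panel_maf = 0.01) {
  stopifnot(inherits(panel, "ld_panel"), half_window_bp > 0,
            is.numeric(zmap), !is.null(names(zmap)))
  ids <- names(zmap)
  v <- panel$variants
  maf <- panel_maf(panel)
  pidx <- match(ids, v$id)
  out <- data.frame(id = ids, z = unname(zmap),
                    n_neighbors = 0L, weight_sum = 0,
                    local_mean = NA_real_, lmi = NA_real_,
                    estimable = FALSE, stringsAsFactors = FALSE)
  in_panel <- !is.na(pidx)
  focal_ok <- in_panel & !is.na(maf[pidx]) & maf[pidx] >= min_panel_maf
  # scored panel variants are the only admissible neighbors
  scored_at <- rep(NA_integer_, nrow(v))
  scored_at[pidx[in_panel]] <- which(in_panel)
  for (k in which(focal_ok)) {
    i <- pidx[k]
    cand <- which(v$chrom == v$chrom[i] &
                  abs(v$pos - v$pos[i]) <= half_window_bp &
                  !is.na(scored_at))
    cand <- setdiff(cand, i)
    cand <- cand[!is.na(maf[cand]) & abs(maf[cand] - maf[i]) <= maf_tolerance]
    if (!length(cand)) next
    w <- .r2_vec(panel$dosage[i, ], panel$dosage[cand, , drop = FALSE])
    usable <- !is.na(w)
    if (!any(usable) || sum(w[usable]) == 0) next
    zj <- out$z[scored_at[cand[usable]]]
    wt <- w[usable]
    out$n_neighbors[k] <- length(wt)
    out$weight_sum[k] <- sum(wt)
    out$local_mean[k] <- sum(zj * wt) / sum(wt)
    out$lmi[k] <- out$z[k] * out$local_mean[k]
    out$estimable[k] <- TRUE
  }
  class(out) <- c("lmi_records", "data.frame")
  out
}

#' Apply the LMI exclusion rules
#'
#' Discards (1) SNPs with a negative LMI — the neighborhood disagrees
#' with the focal OR or is in linkage equilibrium — and (2) SNPs with a
#' non-negative LMI that come from the bottom 50% tail of the ordered
#' transformed OR distribution (z below the median z over all scored
#' SNPs; the boundary value is retained). The two exclusion flags are
#' mutually exclusive.
#'
#' @param records an `lmi_records` data.frame from [compute_lmi()].
#' @return `records` with logical columns `excluded_negative`,
#'   `excluded_bottom_tail` and `retained` added (flags are `NA` for
#'   non-estimable records); the retained subset is
#'   `records[records$retained, ]`.
#' @export
filter_lmi <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("z", "lmi", "estimable") %in% names(records)))
  medz <- stats::median(records$z)
  neg <- records$estimable & records$lmi < 0
  bot <- records$estimable & records$lmi >= 0 & records$z < medz
  records$excluded_negative <- ifelse(records$estimable, neg, NA)
  records$excluded_bottom_tail <- ifelse(records$estimable, bot, NA)
  records$retained <- records$estimable & !neg & !bot
  records
}

#' Select the top fraction of SNPs by LMI
#'
#' Sorts retained records by LMI descending (ties broken by smaller p,
#' then id) and selects the first `floor(fraction * n)`; also reports
#' the implied LMI threshold (the LMI of the last selected SNP).
#'
#' @param records data.frame with columns `id` and `lmi` (typically the
#'   retained subset after [filter_lmi()]); an optional `p` column
#'   breaks ties.
#' @param fraction fraction of records to select (default 0.005, the
#'   top 0.5%).
#' @return A list: `selected` (records with a `rank` column, best LMI =
#'   rank 1), `k` (selection size), `threshold` (LMI at rank k, `NA`
#'   when k = 0).
#' @export
select_top_fraction <- function(records, fraction = 0.005) {
  stopifnot(is.data.frame(records),
            all(c("id", "lmi") %in% names(records)),
            fraction > 0, fraction <= 1)
  n <- nrow(records)
  k <- floor(fraction * n)
  if (k == 0L) {
    warning("selection is empty: floor(fraction * n) = 0")
    sel <- records[integer(0), , drop = FALSE]
    sel$rank <- integer(0)
    return(list(selected = sel, k = 0L, threshold = NA_real_))
  }
  tie_p <- if ("p" %in% names(records)) records$p else rep(0, n)
  ord <- order(-records$lmi, tie_p, records$id)
  sel <- records[ord[seq_len(k)], , drop = FALSE]
  sel$rank <- seq_len(k)
  rownames(sel) <- NULL
  list(selected = sel, k = k, threshold = sel$lmi[k])
}
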