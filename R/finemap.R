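#' Wakefield approximate Bayes factor
#'
#' Closed-form Bayes factor in favor of association for an effect
#' estimate `beta` with standard error `se` under a normal effect prior
#' with variance `prior_w`: with `V = se^2` and `z = beta/se`,
#' `BF = sqrt(V / (V + W)) * exp(z^2 * W / (2 * (V + W)))`. A zero prior
#' variance gives BF = 1 for any z.
#'
#' @param beta effect estimate (log OR scale).
#' @param se standard error (positive).
#' @param prior_w prior variance of the effect (default 0.04, i.e.
#'   prior SD 0.2 on the log-OR scale).
#' @return The Bayes factor (vectorized over `beta`/`se`).
#' @examples
#' wakefield_bf(3, 1)   # 1.1659
#' @export
wakefield_bf <- function(beta, se, prior_w = 0.04) {
  stopifnot(all(se > 0), prior_w >= 0)
  V <- se^2
  z <- beta / se
  sqrt(V / (V + prior_w)) * exp(z^2 * prior_w / (2 * (V + prior_w)))
}

#' Credible set around a prioritized lead SNP
#'
#' Defines the region as the lead plus all scored SNPs within
#' `half_window_bp` with panel LD `r2 > r2_min` to the lead, normalizes
#' Wakefield Bayes factors to posterior probabilities over the region,
#' and takes the smallest posterior-descending prefix whose cumulative
#' posterior reaches `mass`.
#'
#' @param lead_id id of the prioritized SNP (must be in `study` and
#'   estimable in `panel`).
#' @param study a [study_set()] providing beta/se/p for region members.
#' @param panel an [ld_panel()] providing LD to the lead.
#' @param r2_min LD threshold, strict (default 0.1).
#' @param half_window_bp half window in bp (default 500 kb, so the
#'   region spans 1 Mb).
#' @param mass cumulative posterior target (default 0.99).
#' @param prior_w prior variance for [wakefield_bf()].
#' @return A list of class `credible_set`: `lead_id`, `region`
#'   (chrom/start/end), `members` (data.frame id, bf, posterior,
#'   cumulative, in_set sorted by posterior descending), `set_ids`,
#'   `contains_min_p` (whether the region's smallest-p SNP made the
#'   set).
#' @export
credible_set <- function(lead_id, study, panel, r2_min = 0.1,
                         half_window_bp = 500000, mass = 0.99,
                         prior_w = 0.04) {
  stopifnot(inherits(study, "study_set"), inherits(panel, "ld_panel"),
            mass > 0, mass <= 1)
  li <- match(lead_id, study$id)
  if (is.na(li)) stop("lead SNP not in study: ", lead_id)
  pi <- match(lead_id, panel$variants$id)
  if (is.na(pi)) stop("lead SNP not estimable in panel: ", lead_id)
  lead_dos <- panel$dosage[pi, ]
  if (sum(!is.na(lead_dos)) < 2L ||
      stats::var(lead_dos, na.rm = TRUE) == 0)
    stop("lead SNP not estimable in panel: ", lead_id)
  chrom <- study$chrom[li]
  pos <- study$pos[li]
  cand <- which(study$chrom == chrom &
                abs(study$pos - pos) <= half_window_bp)
  cand <- setdiff(cand, li)
  if (length(cand)) {
    cidx <- match(study$id[cand], panel$variants$id)
    ok <- !is.na(cidx)
    r2 <- rep(NA_real_, length(cand))
    if (any(ok))
      r2[ok] <- .r2_vec(lead_dos,
                        panel$dosage[cidx[ok], , drop = FALSE])
    cand <- cand[!is.na(r2) & r2 > r2_min]
  }
  region <- study[c(li, cand), , drop = FALSE]
  bf <- wakefield_bf(region$beta, region$se, prior_w)
  posterior <- bf / sum(bf)
  ord <- order(-posterior, region$id)
  members <- data.frame(id = region$id[ord], p = region$p[ord],
                        bf = bf[ord], posterior = posterior[ord],
                        stringsAsFactors = FALSE)
  members$cumulative <- cumsum(members$posterior)
  k <- match(TRUE, members$cumulative >= mass - 1e-12,
             nomatch = nrow(members))
  members$in_set <- seq_len(nrow(members)) <= k
  min_p_id <- region$id[which.min(region$p)]
  structure(list(lead_id = lead_id,
                 region = list(chrom = chrom,
                               start = max(1L, pos - half_window_bp),
                               end = pos + half_window_bp),
                 members = members,
                 set_ids = members$id[members$in_set],
                 contains_min_p = min_p_id %in%
                   members$id[members$in_set]),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf(
    "<credible_set> lead %s: %d region SNP(s), %d in the set%s\n",
    x$lead_id, nrow(x$members), length(x$set_ids),
    if (x$contains_min_p) " (contains min-p SNP)" else ""))
  invisible(x)
}
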