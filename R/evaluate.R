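#' Median-rank permutation benchmark against known hits
#'
#' Tests whether a set of known hit SNPs sits closer to the top of a
#' prioritized list (rank 1 = best, e.g. largest LMI) than random sets
#' of the same size. The statistic is the median rank of the hits; the
#' null distribution is the median rank of subsets drawn uniformly
#' without replacement from the list. The one-tailed p-value counts
#' null medians at least as good (<=) as the observed one, with the +1
#' correction in sampled mode so p is never exactly zero. When
#' `choose(n, k) <= 10000` an exhaustive mode enumerates every subset.
#'
#' @param ranked_ids character vector, best-first ranking of all scored
#'   SNPs.
#' @param hit_ids known-hit ids; must all appear in `ranked_ids`.
#' @param B number of random sets in sampled mode (default 10000).
#' @param seed integer seed for the random draws.
#' @param method "auto" (exhaustive when feasible), "sampled" or
#'   "exhaustive".
#' @return A list of class `benchmark_result`: `observed_median_rank`,
#'   `null_medians`, `p_one_tailed`, `B` (null sets used), `seed`,
#'   `method`.
#' @export
benchmark_rank_permutation <- function(ranked_ids, hit_ids, B = 10000,
                                       seed = 1,
                                       method = c("auto", "sampled",
                                                  "exhaustive")) {
  method <- match.arg(method)
  n <- length(ranked_ids)
  ranks <- match(hit_ids, ranked_ids)
  if (anyNA(ranks))
    stop("hit id(s) not in ranked list: ",
         paste(hit_ids[is.na(ranks)], collapse = ", "))
  k <- length(ranks)
  stopifnot(k >= 1L, k <= n)
  observed <- stats::median(ranks)
  if (method == "auto")
    method <- if (choose(n, k) <= 10000) "exhaustive" else "sampled"
  if (method == "exhaustive") {
    if (choose(n, k) > 1e6)
      stop("exhaustive enumeration infeasible for choose(", n, ", ", k, ")")
    null_medians <- apply(utils::combn(n, k), 2L, stats::median)
    p <- sum(null_medians <= observed) / length(null_medians)
    B_used <- length(null_medians)
  } else {
    set.seed(seed)
    null_medians <- vapply(seq_len(B), function(b)
      stats::median(sample.int(n, k)), numeric(1))
    p <- (1 + sum(null_medians <= observed)) / (B + 1)
    B_used <- B
  }
  structure(list(observed_median_rank = observed,
                 null_medians = null_medians, p_one_tailed = p,
                 B = B_used, seed = seed, method = method),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> observed median rank %.1f, one-tailed p = %.4g (%s, %d null sets)\n",
    x$observed_median_rank, x$p_one_tailed, x$method, x$B))
  invisible(x)
}

#' Greedy LD clumping to independent signals
#'
#' Iterates records by score descending and keeps a record only if its
#' panel LD with every already-kept record on the same chromosome
#' within `half_window_bp` is below `r2_max`. Distal same-chromosome LD
#' (beyond the window) is treated as zero, as is LD that the panel
#' cannot estimate.
#'
#' @param records data.frame with columns `id` and the score column;
#'   an optional `p` column (then `id`) breaks score ties.
#' @param panel an [ld_panel()] providing positions and LD.
#' @param score_col name of the score column to sort on, descending
#'   (default "lmi"; use e.g. negative log p for 1D pruning).
#' @param r2_max LD threshold, strict `r2 < r2_max` (default 0.2).
#' @param half_window_bp window within which LD is checked (default
#'   500 kb).
#' @return The kept subset of `records`, in score order.
#' @export
prune_independent <- function(records, panel, score_col = "lmi",
                              r2_max = 0.2, half_window_bp = 500000) {
  stopifnot(is.data.frame(records), inherits(panel, "ld_panel"),
            "id" %in% names(records), score_col %in% names(records))
  tie_p <- if ("p" %in% names(records)) records$p else
    rep(0, nrow(records))
  ord <- order(-records[[score_col]], tie_p, records$id)
  x <- records[ord, , drop = FALSE]
  pidx <- match(x$id, panel$variants$id)
  chrom <- panel$variants$chrom[pidx]
  pos <- panel$variants$pos[pidx]
  kept <- integer(0)
  for (i in seq_len(nrow(x))) {
    ok <- TRUE
    if (!is.na(pidx[i]) && length(kept)) {
      near <- kept[!is.na(pidx[kept]) & chrom[kept] == chrom[i] &
                   abs(pos[kept] - pos[i]) <= half_window_bp]
      if (length(near)) {
        r2 <- .r2_vec(panel$dosage[pidx[i], ],
                      panel$dosage[pidx[near], , drop = FALSE])
        ok <- all(is.na(r2) | r2 < r2_max)
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- x[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum comparison of two samples on pooled mid-ranks: exact
#' enumeration when the pooled size is at most 12 and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @param alternative "two.sided" (default), "less" or "greater"
#'   (alternative about x relative to y).
#' @return A list: `statistic` (Mann-Whitney W for x), `p`, `exact`.
#' @export
ranksum_test <- function(x, y,
                         alternative = c("two.sided", "less",
                                         "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  exact <- (length(x) + length(y) <= 12L) &&
    !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of pooled mid-ranks. A constant vector makes the
#' correlation undefined; that is signalled with a warning and `NA`.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return Spearman's rho, or `NA_real_` when undefined.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("undefined correlation: constant input vector")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}
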