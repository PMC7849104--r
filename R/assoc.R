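#' Per-SNP logistic association
#'
#' Fits `y ~ g + covariates` by logistic regression under an additive
#' mode of inheritance (dosage coded 0/1/2) and returns the Wald summary
#' for the dosage term. Non-convergence or quasi-complete separation
#' (diverging |beta| > 20) yields a flagged record with NA statistics
#' rather than an error; rank-deficient covariates are a configuration
#' error.
#'
#' @param y binary outcome vector (1 = case); must not be constant.
#' @param g dosage vector for the SNP.
#' @param covariates optional data.frame or matrix of adjustment
#'   covariates (e.g. age, sex, region indicators, principal
#'   components).
#' @return A one-row data.frame: `beta` (log OR), `se`, `p`, `or`,
#'   `converged`, `flag` ("" , "separation" or "nonconvergence").
#' @examples
#' # saturated 2x2-table fit equals the cross-product OR and Woolf SE
#' y <- rep(c(1, 1, 0, 0), c(20, 80, 10, 90))
#' g <- rep(c(1, 0, 1, 0), c(20, 80, 10, 90))
#' logistic_assoc(y, g)   # beta = log(2.25), se = 0.4167
#' @export
logistic_assoc <- function(y, g, covariates = NULL) {
  stopifnot(length(y) == length(g))
  if (length(unique(y[!is.na(y)])) < 2L) stop("outcome y is constant")
  mm <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    mm <- stats::model.matrix(~ ., data = covariates)
    if (qr(mm)$rank < ncol(mm))
      stop("rank-deficient covariate matrix")
  }
  X <- cbind(`(Intercept)` = 1, g = g)
  if (!is.null(covariates))
    X <- cbind(X, mm[, -1L, drop = FALSE])
  .logit_fit(X, y, term = "g")
}

# IRLS logistic fit via glm.fit on a prebuilt model matrix; returns the
# Wald summary for one term. Separation surfaces as |beta| > 20.
.logit_fit <- function(X, y, term) {
  na_rec <- data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                       or = NA_real_, converged = FALSE, flag = "")
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100)))
  b <- fit$coefficients[term]
  if (is.na(b)) stop("dosage term aliased with covariates")
  if (!fit$converged) { na_rec$flag <- "nonconvergence"; return(na_rec) }
  if (abs(b) > 20) { na_rec$flag <- "separation"; return(na_rec) }
  p1 <- seq_len(fit$qr$rank)
  cov_unscaled <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- sqrt(cov_unscaled[match(term, colnames(X)[fit$qr$pivot[p1]]),
                          match(term, colnames(X)[fit$qr$pivot[p1]])])
  data.frame(beta = unname(b), se = se,
             p = 2 * stats::pnorm(-abs(b) / se),
             or = exp(unname(b)), converged = TRUE, flag = "")
}

#' Genome-wide association scan over a panel
#'
#' Runs [logistic_assoc()] for every panel variant and assembles the
#' results into a [study_set()] (panel MAF attached, monomorphic or
#' flagged SNPs dropped with a message).
#'
#' @param panel an [ld_panel()] holding the study genotypes.
#' @param y binary outcome vector, one entry per panel individual.
#' @param covariates optional covariate data.frame (see
#'   [logistic_assoc()]).
#' @return A [study_set()] of per-SNP summaries.
#' @export
assoc_scan <- function(panel, y, covariates = NULL) {
  stopifnot(inherits(panel, "ld_panel"),
            length(y) == panel$n_individuals)
  v <- panel$variants
  maf <- panel_maf(panel)
  mm <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = covariates)
    if (qr(mm)$rank < ncol(mm))
      stop("rank-deficient covariate matrix")
    mm <- mm[, -1L, drop = FALSE]
  }
  res <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    if (is.na(maf[i]) || maf[i] == 0) next
    X <- cbind(`(Intercept)` = 1, g = panel$dosage[i, ])
    if (!is.null(mm)) X <- cbind(X, mm)
    r <- .logit_fit(X, y, term = "g")
    if (!r$converged) next
    res[[i]] <- cbind(data.frame(id = v$id[i], chrom = v$chrom[i],
                                 pos = v$pos[i],
                                 effect_allele = v$alt[i],
                                 other_allele = v$ref[i],
                                 maf = unname(maf[i])),
                      r[, c("or", "beta", "se", "p")])
  }
  kept <- !vapply(res, is.null, logical(1))
  if (!any(kept)) stop("no SNP produced a usable association fit")
  if (any(!kept))
    message(sum(!kept), " SNP(s) dropped (monomorphic or unstable fit)")
  study_set(do.call(rbind, res[kept]), provenance = "assoc_scan")
}

#' Genomic inflation factor
#'
#' Lambda is the median observed 1-df association chi-square divided by
#' the null chi-square median (0.4549); values near 1 indicate little
#' evidence of confounding-driven inflation.
#'
#' @param p two-sided p-values (converted through the inverse chi-square
#'   survival function); give either `p` or `chisq`.
#' @param chisq 1-df chi-square statistics.
#' @return Lambda (positive scalar).
#' @export
genomic_lambda <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    if (is.null(p)) stop("supply p or chisq")
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  chisq <- chisq[is.finite(chisq)]
  if (!length(chisq)) stop("no finite statistics")
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Random-effects meta-analysis of per-study effects
#'
#' DerSimonian-Laird random-effects pooling of study-level log ORs and
#' standard errors (delegated to \pkg{metafor}). A single study passes
#' through with tau² = 0.
#'
#' @param beta per-study effect estimates (log OR scale).
#' @param se per-study standard errors (positive).
#' @param labels optional study labels.
#' @return A list: `beta` (pooled), `se`, `tau2`, `Q`, `p` (two-sided),
#'   `k`.
#' @examples
#' meta_random_effects(c(0, 2), c(1, 1))  # Q = 2, tau2 = 1, pooled = 1
#' @export
meta_random_effects <- function(beta, se, labels = NULL) {
  stopifnot(length(beta) >= 1L, length(beta) == length(se),
            all(is.finite(beta)), all(is.finite(se)), all(se > 0))
  if (length(beta) == 1L)
    return(list(beta = beta, se = se, tau2 = 0, Q = 0,
                p = 2 * stats::pnorm(-abs(beta) / se), k = 1L))
  fit <- if (is.null(labels))
    metafor::rma(yi = beta, sei = se, method = "DL")
  else metafor::rma(yi = beta, sei = se, method = "DL", slab = labels)
  list(beta = as.numeric(fit$beta), se = fit$se, tau2 = fit$tau2,
       Q = fit$QE, p = fit$pval, k = fit$k)
}
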