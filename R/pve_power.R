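#' Phenotypic variance explained as partial r-squared
#'
#' Fits the covariate-only ("base") ordinary-least-squares model and the
#' model with the variant group's dosages added, on the same complete-case
#' individuals, and reports the proportional reduction of the residual sum
#' of squares: `pve = (rss_base - rss_full) / rss_base`. With a single
#' variant and no covariates this equals the squared Pearson correlation of
#' dosage and trait.
#'
#' @param cohort A `cohort` object.
#' @param covariates Covariate column names of the base model (`NULL` = all;
#'   use `character(0)` for an intercept-only base model).
#' @param snp_group Character vector of variant ids (`chrom:pos:ref:alt`) to
#'   add; a single id gives the per-variant PVE, several give the combined
#'   PVE of the group.
#' @return A list of class `pve_result`: `rss_base`, `rss_full`, `pve`, `n`.
#' @export
pve_partial_r2 <- function(cohort, covariates = NULL, snp_group) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(snp_group) == 0) stop("snp_group must be non-empty")
  idx <- match(snp_group, cohort$variants$id)
  if (anyNA(idx))
    stop("variant(s) not in cohort: ",
         paste(snp_group[is.na(idx)], collapse = ", "))
  y <- cohort$phenotype
  C <- build_covariate_matrix(cohort$covariates, covariates)
  G <- cohort$dosages[, idx, drop = FALSE]
  ok <- !is.na(y) & complete.cases(C) & complete.cases(G)
  yb <- y[ok]
  Xb <- cbind(1, C[ok, , drop = FALSE])
  qb <- qr(Xb)
  if (qb$rank < ncol(Xb)) stop("base model is rank deficient")
  rss_base <- sum(qr.resid(qb, yb)^2)
  Xf <- cbind(Xb, G[ok, , drop = FALSE])
  rss_full <- sum(qr.resid(qr(Xf), yb)^2)
  pve <- (rss_base - rss_full) / rss_base
  structure(list(rss_base = rss_base, rss_full = rss_full,
                 pve = max(0, min(1, pve)), n = sum(ok)),
            class = "pve_result")
}

#' @export
print.pve_result <- function(x, ...) {
  cat(sprintf("pve_result: partial r2 = %.4f (n = %d)\n", x$pve, x$n))
  invisible(x)
}

#' Analytic power to detect a variant of given PVE
#'
#' Power of the 1-df association test at significance level `alpha` for a
#' variant explaining a fraction `pve` of the (covariate-adjusted) trait
#' variance in a sample of size `n`: the upper-tail probability of a
#' noncentral chi-square with 1 degree of freedom and noncentrality
#' `lambda = n * pve / (1 - pve)` beyond the central critical value. The
#' `ncp = "n_pve"` alternative uses `lambda = n * pve` (the convention
#' without residual-variance rescaling).
#'
#' @param n Sample size.
#' @param pve Variance fraction explained, in `[0, 1)`.
#' @param alpha Significance level (genome-wide conventionally `5e-8`).
#' @param ncp Noncentrality convention, `"pve_ratio"` (default) or
#'   `"n_pve"`.
#' @return A list of class `power_spec`: `n`, `pve`, `alpha`, `ncp`,
#'   `power`.
#' @examples
#' power_detect(324, 0.12, 5e-8)$power  # about 0.88
#' @export
power_detect <- function(n, pve, alpha = 5e-8,
                         ncp = c("pve_ratio", "n_pve")) {
  ncp <- match.arg(ncp)
  if (pve < 0 || pve >= 1) stop("pve must be in [0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  lambda <- if (ncp == "pve_ratio") n * pve / (1 - pve) else n * pve
  crit <- qchisq(alpha, df = 1, lower.tail = FALSE)
  power <- pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
  structure(list(n = n, pve = pve, alpha = alpha, ncp = lambda,
                 power = power), class = "power_spec")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf(
    "power_spec: n = %d, pve = %.3f, alpha = %.2g -> power = %.3f\n",
    x$n, x$pve, x$alpha, x$power))
  invisible(x)
}
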