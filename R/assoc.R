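#' Association-scan configuration
#'
#' @param covariates Character vector of covariate column names to adjust
#'   for; factors are expanded to dummies. `NULL` means all columns of the
#'   cohort's covariate table.
#' @param transform `"raw"` to analyse the phenotype as measured, `"int"` to
#'   apply the rank-based inverse normal transform first (sensitivity
#'   analysis for skewed bounded traits).
#' @param sig_threshold Genome-wide significance level (reported, not used to
#'   filter), default `5e-8`.
#' @param x_male_coding Apply the X-inactivation dosage coding: male
#'   X-chromosome genotypes count the single allele twice (0 or 2). Male X
#'   dosages already stored on the 0-2 scale are left unchanged; values on
#'   the hemizygous 0/1 allele-count scale are doubled.
#' @param missing `"complete"` drops individuals with a missing dosage for
#'   that variant (per-variant complete case); `"mean"` imputes the
#'   in-sample mean dosage.
#' @return An object of class `assoc_config`.
#' @export
assoc_config <- function(covariates = NULL,
                         transform = c("raw", "int"),
                         sig_threshold = 5e-8,
                         x_male_coding = TRUE,
                         missing = c("complete", "mean")) {
  transform <- match.arg(transform)
  missing <- match.arg(missing)
  if (sig_threshold <= 0 || sig_threshold >= 1)
    stop("sig_threshold must be in (0, 1)")
  structure(list(covariates = covariates, transform = transform,
                 sig_threshold = sig_threshold,
                 x_male_coding = isTRUE(x_male_coding), missing = missing),
            class = "assoc_config")
}

#' X-chromosome dosage coding under X-inactivation
#'
#' Males are hemizygous on the non-pseudoautosomal X; under the
#' X-inactivation assumption their single allele is counted twice, so a male
#' carrying the reference allele scores 0 and one carrying the alternate
#' allele scores 2. Females keep the usual 0/1/2 coding. Accepts VCF-style
#' genotype strings (`"0"`, `"1"`, `"0/0"`, `"0/1"`, `"1/1"`, `"0|1"`, ...)
#' or numeric allele counts; a heterozygous male call is an error (it should
#' have been removed in QC).
#'
#' @param genotype Character genotype string(s) or numeric hard call(s).
#' @param sex Character/factor vector, `"male"` or `"female"` (recycled).
#' @return Numeric dosage(s) in `{0, 1, 2}`.
#' @examples
#' encode_dosage_x("1", "male")    # 2
#' encode_dosage_x("0/1", "female") # 1
#' @export
encode_dosage_x <- function(genotype, sex) {
  sex <- as.character(rep_len(sex, length(genotype)))
  if (!all(sex %in% c("male", "female"))) stop("sex must be male/female")
  if (is.character(genotype)) {
    alt_count <- function(gt) {
      alleles <- strsplit(gsub("\\|", "/", gt), "/")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1") + 0 * sum(alleles == "0")
    }
    n_alt <- vapply(genotype, alt_count, numeric(1), USE.NAMES = FALSE)
    n_alleles <- vapply(genotype, function(gt) {
      length(strsplit(gsub("\\|", "/", gt), "/")[[1]])
    }, integer(1), USE.NAMES = FALSE)
  } else {
    n_alt <- as.numeric(genotype)
    n_alleles <- ifelse(sex == "male", ifelse(n_alt == 2, 2L, 1L), 2L)
  }
  male <- sex == "male"
  het_male <- male & !is.na(n_alt) & n_alleles == 2 & n_alt == 1
  if (any(het_male))
    stop("heterozygous male X call: remove in QC before encoding")
  out <- n_alt
  out[male & n_alleles == 1] <- 2 * n_alt[male & n_alleles == 1]
  out
}

# core OLS fit: returns beta/se/p for the column of interest (index 2)
ols_term <- function(X, y) {
  n <- length(y)
  p <- ncol(X)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(list(beta = NA_real_, se = NA_real_, p = 1, df = NA))
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y)))
  res <- y - X %*% beta
  df <- n - p
  sigma2 <- sum(res^2) / df
  inv22 <- chol2inv(ch)[2, 2]
  se <- sqrt(sigma2 * inv22)
  tval <- beta[2] / se
  list(beta = beta[2], se = se,
       p = if (is.nan(tval)) 1 else 2 * pt(-abs(tval), df), df = df)
}

build_covariate_matrix <- function(covariates, names = NULL) {
  if (is.null(names)) names <- colnames(covariates)
  if (length(names) == 0) return(matrix(numeric(0), nrow(covariates), 0))
  missing_cov <- setdiff(names, colnames(covariates))
  if (length(missing_cov) > 0)
    stop("covariates not found: ", paste(missing_cov, collapse = ", "))
  mm <- stats::model.matrix(~., data = covariates[, names, drop = FALSE])
  mm[, -1, drop = FALSE]  # model.matrix keeps complete rows only if no NA
}

#' Genome-wide per-variant linear association scan
#'
#' For every variant, ordinary least squares of the (optionally
#' inverse-normal-transformed) trait on alt-allele dosage plus intercept and
#' covariates; two-sided p-values from the t distribution with
#' `n_used - n_predictors - 1` degrees of freedom. Variants monomorphic
#' in-sample (or otherwise rank-deficient) are emitted with `NA` beta/se and
#' `p = 1`. When no dosages are missing the scan uses one-shot
#' residualization of trait and dosages on the covariates
#' (Frisch-Waugh), which is algebraically identical to the per-variant fit.
#'
#' @param cohort A `cohort` object (post-QC).
#' @param config An [assoc_config()].
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `beta`,
#'   `se`, `p`, `n`, `maf`, sorted by `(chrom, pos)` — the summary-statistics
#'   dialect consumed by the enrichment and polygenic-score stages.
#' @export
run_gwas <- function(cohort, config = assoc_config()) {
  stopifnot(inherits(cohort, "cohort"))
  y <- cohort$phenotype
  if (all(is.na(y))) stop("all-missing phenotype")
  if (config$transform == "int") y <- inverse_normal_transform(y)

  C <- build_covariate_matrix(cohort$covariates, config$covariates)
  D <- cohort$dosages
  v <- cohort$variants
  male <- cohort$sex == "male"

  if (config$x_male_coding && any(v$chrom == "X") && any(male)) {
    xj <- which(v$chrom == "X")
    mx <- D[male, xj, drop = FALSE]
    if (all(mx <= 1, na.rm = TRUE)) D[male, xj] <- 2 * mx
  }

  base_ok <- !is.na(y) & complete.cases(C)
  V <- ncol(D)
  beta <- se <- rep(NA_real_, V)
  p <- rep(1, V)
  n_used <- integer(V)
  maf <- rep(NA_real_, V)

  no_missing <- !anyNA(D[base_ok, , drop = FALSE])
  if (config$missing == "mean" || no_missing) {
    yb <- y[base_ok]
    Cb <- cbind(1, C[base_ok, , drop = FALSE])
    Db <- D[base_ok, , drop = FALSE]
    if (!no_missing) {
      mu <- colMeans(Db, na.rm = TRUE)
      idx <- which(is.na(Db), arr.ind = TRUE)
      Db[idx] <- mu[idx[, 2]]
    }
    qrC <- qr(Cb)
    ry <- qr.resid(qrC, yb)
    RG <- qr.resid(qrC, Db)
    gss <- colSums(RG^2)
    n <- length(yb)
    df <- n - ncol(Cb) - 1
    bj <- as.numeric(crossprod(RG, ry)) / gss
    rss <- sum(ry^2) - bj^2 * gss
    sej <- sqrt(pmax(rss, 0) / df / gss)
    tj <- bj / sej
    ok <- gss > 1e-12
    beta[ok] <- bj[ok]; se[ok] <- sej[ok]
    p[ok] <- 2 * pt(-abs(tj[ok]), df)
    n_used[] <- n
    af <- colMeans(Db) / 2
    maf[] <- pmin(af, 1 - af)
  } else {
    for (j in seq_len(V)) {
      ok <- base_ok & !is.na(D[, j])
      g <- D[ok, j]
      n_used[j] <- sum(ok)
      if (n_used[j] < 3) next
      af <- mean(g) / 2
      maf[j] <- min(af, 1 - af)
      if (var(g) < 1e-12) next
      X <- cbind(1, g, C[ok, , drop = FALSE])
      fit <- ols_term(X, y[ok])
      beta[j] <- fit$beta; se[j] <- fit$se; p[j] <- fit$p
    }
  }
  p <- pmax(p, .Machine$double.xmin)

  out <- data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    beta = beta, se = se, p = p, n = n_used, maf = maf,
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$pos), , drop = FALSE]
}
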