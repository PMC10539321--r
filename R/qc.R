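#' Quality-control thresholds
#'
#' Defaults follow common practice for array-genotyped, imputed cohorts:
#' variant and sample call rate at least 90%, Hardy-Weinberg flag at
#' P < 1e-4 (flagged but retained), post-imputation MAF > 1% and imputation
#' quality r2 > 0.4, and kinship coefficient below 0.088 for the unrelated
#' set.
#'
#' @param min_call_rate Minimum variant/sample call rate.
#' @param hwe_p_flag Significance level below which a variant is flagged
#'   (not removed) for Hardy-Weinberg disequilibrium.
#' @param min_maf Minimum minor allele frequency.
#' @param min_info_r2 Minimum imputation-quality r2.
#' @param kinship_threshold Kinship coefficient above which a pair counts as
#'   related.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, hwe_p_flag = 1e-4,
                          min_maf = 0.01, min_info_r2 = 0.4,
                          kinship_threshold = 0.088) {
  vals <- c(min_call_rate, hwe_p_flag, min_maf, min_info_r2, kinship_threshold)
  if (any(vals <= 0) || any(vals >= 1))
    stop("all thresholds must lie in (0, 1)")
  structure(list(min_call_rate = min_call_rate, hwe_p_flag = hwe_p_flag,
                 min_maf = min_maf, min_info_r2 = min_info_r2,
                 kinship_threshold = kinship_threshold),
            class = "qc_thresholds")
}

#' Exact conditional Hardy-Weinberg equilibrium test
#'
#' Conditions on the observed sample size and minor-allele count and sums the
#' probabilities of every heterozygote configuration whose conditional
#' probability does not exceed that of the observed one (two-sided exact
#' test). Preferred over the chi-square approximation because flagging at
#' stringent levels involves rare genotype classes where the approximation
#' fails.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return The exact p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(4, 0, 1)  # 5/45
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_alt <- n_het + 2 * n_hom_alt
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)
  # attainable heterozygote counts share the parity of the minor-allele count
  h <- seq(n_minor %% 2, n_minor, by = 2)
  hom_minor <- (n_minor - h) / 2
  hom_major <- n - h - hom_minor
  keep <- hom_major >= 0
  h <- h[keep]; hom_minor <- hom_minor[keep]; hom_major <- hom_major[keep]
  logp <- lfactorial(n) - lfactorial(hom_major) - lfactorial(h) -
    lfactorial(hom_minor) + h * log(2) +
    lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Apply variant- and sample-level QC filters
#'
#' Removes variants failing call-rate, MAF or imputation-quality filters and
#' individuals failing the call-rate filter; variants out of Hardy-Weinberg
#' equilibrium at the flag level are retained but listed in the report.
#' Hard-call genotype counts for the HWE test are taken from dosages that are
#' whole numbers; dosage-coded (fractional) variants are not HWE-tested.
#'
#' @param cohort A `cohort` object.
#' @param thresholds A [qc_thresholds()].
#' @return A list with the filtered `cohort` and a `report` (class
#'   `qc_report`) tallying removals per rule and listing flagged HWE
#'   variants.
#' @export
apply_variant_filters <- function(cohort, thresholds = qc_thresholds()) {
  stopifnot(inherits(cohort, "cohort"), inherits(thresholds, "qc_thresholds"))
  v <- cohort$variants
  d <- cohort$dosages
  call_rate <- colMeans(!is.na(d))

  fail_call <- call_rate < thresholds$min_call_rate
  maf_obs <- v$maf
  fail_maf <- pmin(maf_obs, 1 - maf_obs) < thresholds$min_maf
  fail_info <- v$info_r2 <= thresholds$min_info_r2
  keep_var <- !(fail_call | fail_maf | fail_info)

  # HWE: flag, never remove
  flagged <- character(0)
  hwe_p <- rep(NA_real_, nrow(v))
  for (j in which(keep_var)) {
    g <- d[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0 || any(g != round(g))) next
    # autosomal test only; X males would distort genotype counts
    if (v$chrom[j] == "X") next
    hwe_p[j] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  flagged <- v$id[!is.na(hwe_p) & hwe_p < thresholds$hwe_p_flag]

  d2 <- d[, keep_var, drop = FALSE]
  ind_call <- rowMeans(!is.na(d2))
  keep_ind <- ind_call >= thresholds$min_call_rate

  out <- cohort
  out$dosages <- d2[keep_ind, , drop = FALSE]
  out$variants <- v[keep_var, , drop = FALSE]
  out$variants$call_rate <- colMeans(!is.na(out$dosages))
  out$phenotype <- cohort$phenotype[keep_ind]
  out$covariates <- cohort$covariates[keep_ind, , drop = FALSE]
  out$sex <- cohort$sex[keep_ind]

  if (ncol(out$dosages) == 0 || nrow(out$dosages) == 0)
    warning("cohort is empty after filtering")

  report <- structure(list(
    n_variants_in = nrow(v),
    n_individuals_in = nrow(d),
    removed_variants = list(
      call_rate = sum(fail_call),
      maf = sum(fail_maf & !fail_call),
      info_r2 = sum(fail_info & !fail_call & !fail_maf)
    ),
    removed_individuals = list(call_rate = sum(!keep_ind)),
    hwe_flagged = flagged,
    retained_variants = v$id[keep_var],
    retained_individuals = rownames(d)[keep_ind]
  ), class = "qc_report")

  list(cohort = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d/%d variants retained, %d/%d individuals retained, %d HWE-flagged\n",
    length(x$retained_variants), x$n_variants_in,
    length(x$retained_individuals), x$n_individuals_in,
    length(x$hwe_flagged)))
  invisible(x)
}

#' Select a pairwise-unrelated set of individuals
#'
#' Greedy vertex removal on the relatedness graph: while any pair has
#' kinship at or above the threshold, drop the individual with the largest
#' number of above-threshold ties, breaking ties by higher row index. The
#' retained set has no related pair; greediness makes the result
#' deterministic and near-maximal.
#'
#' @param kinship Symmetric numeric matrix of kinship coefficients (the
#'   diagonal is ignored). Row/column names, if present, name individuals.
#' @param threshold Kinship at or above which a pair counts as related.
#' @return Character vector (or integer indices when unnamed) of retained
#'   individuals, in original order.
#' @export
select_unrelated <- function(kinship, threshold = 0.088) {
  kinship <- as.matrix(kinship)
  if (nrow(kinship) != ncol(kinship) ||
      !isTRUE(all.equal(kinship, t(kinship), tolerance = 1e-8)))
    stop("kinship matrix must be square and symmetric")
  n <- nrow(kinship)
  adj <- kinship >= threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    drop_i <- max(which(deg == max(deg)))  # tie -> higher row index
    alive[drop_i] <- FALSE
    adj[drop_i, ] <- FALSE
    adj[, drop_i] <- FALSE
  }
  ids <- rownames(kinship) %||% seq_len(n)
  ids[alive]
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their Blom-offset ranks,
#' `qnorm((r - 3/8) / (m + 1/4))`, with average ranks for ties; missing
#' values stay missing. Standard sensitivity transform for skewed bounded
#' traits.
#'
#' @param values Numeric vector (NA allowed).
#' @param offset Rank offset; 3/8 is the Blom convention.
#' @return Numeric vector of the same length.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  m <- sum(ok)
  if (m < 3) stop("need at least 3 non-missing values")
  if (length(unique(values[ok])) == 1)
    stop("transform undefined: all values identical")
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - offset) / (m - 2 * offset + 1))
  out
}
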