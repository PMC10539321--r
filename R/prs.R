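#' Clumping parameters
#'
#' @param r2_threshold LD r-squared at or above which a neighbour of an
#'   index variant is removed, in `(0, 1]`.
#' @param window_kb Physical half-window around the index variant, in
#'   kilobases.
#' @param p_threshold Inclusion p-value threshold applied before clumping.
#' @return An object of class `clump_params`.
#' @export
clump_params <- function(r2_threshold = 0.1, window_kb = 250,
                         p_threshold = 1) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]")
  if (window_kb <= 0) stop("window_kb must be positive")
  structure(list(r2_threshold = r2_threshold, window_kb = window_kb,
                 p_threshold = p_threshold), class = "clump_params")
}

# r2 accessor: `ld` is either a named square r2 matrix or a dosage matrix
# (individuals x variants, columns named by variant id) from which squared
# Pearson correlations are computed on demand.
ld_r2_fun <- function(ld) {
  if (nrow(ld) == ncol(ld) && !is.null(rownames(ld)) &&
      identical(rownames(ld), colnames(ld))) {
    function(a, b) ld[a, b]
  } else {
    function(a, b) {
      r <- suppressWarnings(cor(ld[, a], ld[, b],
                                use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      r^2
    }
  }
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the remaining variant with the smallest p-value (ties
#' broken by chromosome then position) as an index variant and removes all
#' remaining variants on the same chromosome within the physical window
#' whose LD r-squared with the index is at or above the threshold. Only
#' variants with `p <= p_threshold` enter. The result does not depend on the
#' input row order.
#'
#' @param stats Summary statistics (`chrom`, `pos`, `ref`, `alt`, `p`, ...).
#' @param ld LD source: a square r-squared matrix with row/column names equal
#'   to variant ids (`chrom:pos:ref:alt`), or a reference dosage matrix with
#'   those column names. Variants absent from the LD source are dropped with
#'   a warning.
#' @param params A [clump_params()].
#' @return The rows of `stats` retained as index variants, sorted by
#'   `(chrom, pos)`.
#' @export
ld_clump <- function(stats, ld, params = clump_params()) {
  stopifnot(inherits(params, "clump_params"))
  if (nrow(stats) == 0) {
    warning("empty summary statistics: empty clump result")
    return(stats)
  }
  stats$id <- variant_ids(stats)
  known <- if (is.null(dim(ld))) character(0) else colnames(ld)
  absent <- setdiff(stats$id, known)
  if (length(absent) > 0) {
    warning(length(absent), " variant(s) absent from the LD source dropped")
    stats <- stats[stats$id %in% known, , drop = FALSE]
  }
  stats <- stats[stats$p <= params$p_threshold, , drop = FALSE]
  if (nrow(stats) == 0) {
    warning("no variants pass p_threshold: empty clump result")
    return(stats)
  }
  r2 <- ld_r2_fun(ld)
  # canonical order makes the pass independent of input row order
  stats <- stats[order(stats$p, stats$chrom, stats$pos), , drop = FALSE]
  alive <- rep(TRUE, nrow(stats))
  index <- logical(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    if (!alive[i]) next
    index[i] <- TRUE
    near <- which(alive & !index &
                    stats$chrom == stats$chrom[i] &
                    abs(stats$pos - stats$pos[i]) <= params$window_kb * 1000)
    if (length(near) > 0) {
      r2v <- as.numeric(r2(stats$id[i], stats$id[near]))
      alive[near[r2v >= params$r2_threshold]] <- FALSE
    }
  }
  out <- stats[index, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

is_strand_ambiguous <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  toupper(alt) == comp[toupper(ref)]
}

#' Build centred polygenic scores from a weight model
#'
#' Each individual's raw score is the sum over model variants of the
#' effect-allele dosage times the additive-scale weight (log odds ratio for
#' binary base traits, beta for quantitative ones); raw scores are then
#' centred to the cohort mean. When the model's effect allele is the
#' cohort's reference allele the dosage is flipped (`2 - dosage`).
#' Strand-ambiguous A/T and G/C variants are dropped with a warning, as are
#' variants whose alleles cannot be reconciled. Missing dosages contribute
#' the in-sample mean dosage times the weight.
#'
#' @param model `data.frame` with `chrom`, `pos`, `ref`, `alt`,
#'   `effect_allele`, `weight` (e.g. clumped+thresholded base summary
#'   statistics with `weight = beta`).
#' @param cohort A `cohort` object.
#' @return A list with `scores` (named, centred, sums to zero),
#'   `n_variants_used`, and `dropped` (reasons per dropped variant).
#' @export
build_score <- function(model, cohort) {
  stopifnot(inherits(cohort, "cohort"))
  v <- cohort$variants
  key_c <- paste(v$chrom, v$pos, sep = ":")
  key_m <- paste(model$chrom, model$pos, sep = ":")
  j <- match(key_m, key_c)
  dropped <- character(0)

  use <- !is.na(j)
  if (any(!use)) dropped <- c(dropped, setNames(
    rep("absent from cohort", sum(!use)), key_m[!use]))

  flip <- rep(FALSE, nrow(model))
  ambiguous <- rep(FALSE, nrow(model))
  for (r in which(use)) {
    ca <- v$alt[j[r]]; cr <- v$ref[j[r]]; ea <- model$effect_allele[r]
    if (is_strand_ambiguous(cr, ca)) { ambiguous[r] <- TRUE; next }
    if (ea == ca) flip[r] <- FALSE
    else if (ea == cr) flip[r] <- TRUE
    else { use[r] <- FALSE
           dropped <- c(dropped, setNames("allele mismatch", key_m[r])) }
  }
  if (any(ambiguous)) {
    warning(sum(ambiguous), " strand-ambiguous variant(s) dropped")
    dropped <- c(dropped, setNames(rep("strand-ambiguous", sum(ambiguous)),
                                   key_m[ambiguous]))
    use <- use & !ambiguous
  }
  if (!any(use)) stop("no overlapping variants between model and cohort")

  D <- cohort$dosages[, j[use], drop = FALSE]
  mu <- colMeans(D, na.rm = TRUE)
  na_idx <- which(is.na(D), arr.ind = TRUE)
  if (nrow(na_idx) > 0) D[na_idx] <- mu[na_idx[, 2]]
  fl <- flip[use]
  if (any(fl)) D[, fl] <- 2 - D[, fl, drop = FALSE]
  raw <- as.numeric(D %*% model$weight[use])
  scores <- raw - mean(raw)
  names(scores) <- rownames(cohort$dosages)
  list(scores = scores, n_variants_used = sum(use), dropped = dropped)
}

#' Covariate-adjusted association of a polygenic score with the trait
#'
#' Ordinary least squares of the trait on the centred score plus covariates,
#' with the Bonferroni-corrected significance level for the family of scores
#' tested reported alongside (e.g. five scores give `0.05/5 = 0.01`).
#'
#' @param scores Named numeric vector of per-individual scores (as from
#'   [build_score()]).
#' @param cohort A `cohort` object.
#' @param covariates Covariate column names to adjust for (`NULL` = all).
#' @param n_scores_in_family Number of scores in the tested family.
#' @param family_alpha Family-wise significance level (default 0.05).
#' @return A list of class `score_assoc`: `beta`, `se`, `p`, `n`,
#'   `bonferroni_alpha`, `significant`.
#' @export
associate_score <- function(scores, cohort, covariates = NULL,
                            n_scores_in_family = 1, family_alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  if (sd(scores) < 1e-12) stop("constant score vector")
  y <- cohort$phenotype
  C <- build_covariate_matrix(cohort$covariates, covariates)
  ok <- !is.na(y) & complete.cases(C) & !is.na(scores)
  X <- cbind(1, scores[ok], C[ok, , drop = FALSE])
  fit <- ols_term(X, y[ok])
  alpha <- family_alpha / n_scores_in_family
  structure(list(beta = fit$beta, se = fit$se,
                 p = max(fit$p, .Machine$double.xmin), n = sum(ok),
                 bonferroni_alpha = alpha,
                 significant = fit$p < alpha),
            class = "score_assoc")
}

#' @export
print.score_assoc <- function(x, ...) {
  cat(sprintf(
    "score_assoc: beta = %.4g (se %.4g), p = %.3g, n = %d, alpha = %.3g\n",
    x$beta, x$se, x$p, x$n, x$bonferroni_alpha))
  invisible(x)
}
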