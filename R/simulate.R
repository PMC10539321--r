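#' Simulation configuration for a synthetic GWAS cohort
#'
#' Bundles and validates every knob of [simulate_cohort()]. The defaults
#' emulate the design of a single-cohort endophenotype GWAS: a few hundred
#' individuals, LD-block-structured biallelic dosages with a realistic allele
#' frequency spectrum, a bounded right-skewed 8-item questionnaire phenotype
#' (items scored 1-4, total 8-32), and the usual clinical covariates (sex,
#' genotyping batch, age, ancestry axes, an ordinal seizure-frequency
#' category).
#'
#' @param n_individuals Number of individuals.
#' @param n_variants Number of biallelic variants.
#' @param n_blocks Number of independent LD blocks; variants are split into
#'   contiguous blocks of near-equal size, one block per chromosome label
#'   (cycling through `"1".."22"`).
#' @param rho Within-block adjacent-variant latent correlation in `[0, 1)`;
#'   the latent haplotype process is first-order autoregressive, so variants
#'   `i`, `j` in a block have latent correlation `rho^|i-j|`.
#' @param maf_range Length-2 numeric, lower/upper bound of the uniform minor
#'   allele frequency spectrum, in `(0, 0.5]`.
#' @param causal_spec `data.frame` with columns `index` (variant index) and
#'   `pve` (target marginal phenotypic variance explained, relative to the
#'   covariate-adjusted trait); may have zero rows. PVE fractions must sum to
#'   below 1.
#' @param covariate_spec Named list of covariate descriptors; see Details.
#' @param phenotype_mode `"continuous"` (latent trait reported directly on a
#'   questionnaire-like scale) or `"bis_like"` (latent trait cut into 8
#'   ordinal items scored 1-4 and summed, giving integers in 8..32).
#' @param miss_rate Fraction of dosages set missing completely at random.
#' @param x_block If `TRUE`, the last LD block is placed on chromosome `"X"`
#'   and males carry a single haplotype, stored as dosage 0/2 under the
#'   X-inactivation coding.
#' @param seed Integer seed; all randomness flows from it.
#'
#' @details `covariate_spec` entries: `sex_p_male` (Bernoulli probability of
#'   male), `n_batches` (categorical genotyping batch), `age_range` (uniform
#'   age at consent, years), `n_ancestry_axes` (standard-normal ancestry
#'   axes), `seizure_levels` (number of ordinal seizure-frequency levels) and
#'   `seizure_probs` (their probabilities). Effects of these covariates on
#'   the trait are fixed, modest, and documented in the methods vignette.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 324,
                       n_variants = 1000,
                       n_blocks = 20,
                       rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       causal_spec = data.frame(index = integer(), pve = numeric()),
                       covariate_spec = list(),
                       phenotype_mode = c("bis_like", "continuous"),
                       miss_rate = 0,
                       x_block = FALSE,
                       seed = 1L) {
  phenotype_mode <- match.arg(phenotype_mode)
  causal_spec <- as.data.frame(causal_spec)
  if (nrow(causal_spec) > 0 && !all(c("index", "pve") %in% names(causal_spec)))
    stop("causal_spec needs columns 'index' and 'pve'")
  if (sum(causal_spec$pve) >= 1)
    stop("infeasible causal_spec: target PVE fractions must sum to < 1")
  if (nrow(causal_spec) > 0 &&
      (any(causal_spec$index < 1) || any(causal_spec$index > n_variants)))
    stop("causal index out of range 1..n_variants")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be ordered bounds in (0, 0.5]")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (n_blocks > n_variants) stop("n_blocks must be <= n_variants")
  if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate must be in [0, 1)")

  cov_default <- list(
    sex_p_male = 0.35, n_batches = 4L, age_range = c(18, 60),
    n_ancestry_axes = 3L, seizure_levels = 4L,
    seizure_probs = c(0.4, 0.3, 0.2, 0.1)
  )
  covariate_spec <- modifyList(cov_default, covariate_spec)
  if (length(covariate_spec$seizure_probs) != covariate_spec$seizure_levels)
    stop("seizure_probs length must equal seizure_levels")

  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    n_blocks = as.integer(n_blocks),
    rho = rho, maf_range = maf_range, causal_spec = causal_spec,
    covariate_spec = covariate_spec, phenotype_mode = phenotype_mode,
    miss_rate = miss_rate, x_block = isTRUE(x_block),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# AR(1) latent Gaussian haplotype block: n haplotypes x m variants.
ar1_latent <- function(n, m, rho) {
  z <- matrix(rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * z[, j]
  }
  z
}

#' Simulate an LD-structured genotype-phenotype cohort
#'
#' Haplotypes are realised by thresholding a stationary first-order
#' autoregressive latent Gaussian process within each LD block (alt allele
#' carried where the latent value falls below the allele-frequency quantile),
#' and summed in pairs to dosages, so every variant is in Hardy-Weinberg
#' equilibrium at its drawn frequency and adjacent variants within a block
#' are correlated. The phenotype is a sum of planted standardized genetic
#' effects (each scaled so its marginal PVE relative to the
#' covariate-adjusted trait equals the target), fixed covariate effects, and
#' Gaussian noise; in `bis_like` mode the latent trait is cut into 8 ordinal
#' items scored 1-4 and summed.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort`: a list with elements
#'   `dosages` (individuals x variants matrix, values in 0..2, `NA` allowed),
#'   `variants` (`data.frame`: `chrom`, `pos`, `ref`, `alt`, `maf`,
#'   `info_r2`, `call_rate`), `phenotype` (numeric; integers in 8..32 in
#'   `bis_like` mode), `covariates` (`data.frame`), `sex` (factor
#'   male/female), and the `config` used.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_individuals
    V <- config$n_variants
    cs <- config$covariate_spec

    # variant frame: blocks -> chromosomes, increasing positions
    block <- sort(rep_len(seq_len(config$n_blocks), V))
    chrom_of_block <- as.character(rep_len(1:22, config$n_blocks))
    if (config$x_block) chrom_of_block[config$n_blocks] <- "X"
    chrom <- chrom_of_block[block]
    pos <- integer(V)
    for (b in seq_len(config$n_blocks)) {
      idx <- which(block == b)
      pos[idx] <- 1e6 + seq_along(idx) * 2000L
    }
    maf <- runif(V, config$maf_range[1], config$maf_range[2])
    # avoid strand-ambiguous (complementary) ref/alt pairs, as array
    # pipelines typically remove them before analysis
    ref <- sample(c("A", "C", "G", "T"), V, replace = TRUE)
    alt <- ifelse(ref %in% c("A", "T"),
                  sample(c("C", "G"), V, replace = TRUE),
                  sample(c("A", "T"), V, replace = TRUE))
    alleles <- cbind(ref, alt)

    sex <- factor(ifelse(runif(n) < cs$sex_p_male, "male", "female"),
                  levels = c("female", "male"))
    male <- sex == "male"

    dosages <- matrix(0, n, V)
    thr <- qnorm(maf)
    for (b in seq_len(config$n_blocks)) {
      idx <- which(block == b)
      m <- length(idx)
      h1 <- ar1_latent(n, m, config$rho) < rep(thr[idx], each = n)
      h2 <- ar1_latent(n, m, config$rho) < rep(thr[idx], each = n)
      g <- h1 + h2
      if (config$x_block && chrom_of_block[b] == "X" && any(male)) {
        # males are hemizygous: one haplotype, coded 0/2 under X-inactivation
        g[male, ] <- 2 * h1[male, , drop = FALSE]
      }
      dosages[, idx] <- g
    }

    covariates <- data.frame(
      sex_male = as.numeric(male),
      batch = factor(sample.int(cs$n_batches, n, replace = TRUE)),
      age = runif(n, cs$age_range[1], cs$age_range[2]),
      seizure_freq = sample.int(cs$seizure_levels, n, replace = TRUE,
                                prob = cs$seizure_probs) - 1L
    )
    for (k in seq_len(cs$n_ancestry_axes))
      covariates[[paste0("pc", k)]] <- rnorm(n)

    # covariate effects on the latent trait (fixed, modest)
    cov_eff <- with(covariates,
      0.30 * sex_male + 0.012 * (age - mean(cs$age_range)) +
        0.25 * seizure_freq)
    for (k in seq_len(cs$n_ancestry_axes))
      cov_eff <- cov_eff + 0.10 * covariates[[paste0("pc", k)]]

    # planted genetic effects: standardized-dosage convention, residual
    # variance of (genetic + noise) fixed at 1 so marginal PVE = target
    gen_eff <- numeric(n)
    if (nrow(config$causal_spec) > 0) {
      for (r in seq_len(nrow(config$causal_spec))) {
        j <- config$causal_spec$index[r]
        f <- maf[j]
        g_std <- (dosages[, j] - 2 * f) / sqrt(2 * f * (1 - f))
        gen_eff <- gen_eff + sqrt(config$causal_spec$pve[r]) * g_std
      }
    }
    noise_sd <- sqrt(1 - sum(config$causal_spec$pve))
    latent <- cov_eff + gen_eff + rnorm(n, sd = noise_sd)

    if (config$phenotype_mode == "bis_like") {
      # 8 items: shared latent loading sqrt(0.5) + item noise, cut into
      # 4 ordered categories at right-skewing quantiles
      centred <- latent - mean(latent)
      breaks <- qnorm(c(0.5, 0.8, 0.95))
      items <- matrix(0L, n, 8)
      a <- sqrt(0.5)
      for (k in 1:8) {
        lat_k <- a * centred / sd(centred) + sqrt(1 - a^2) * rnorm(n)
        items[, k] <- 1L + findInterval(lat_k, breaks)
      }
      phenotype <- as.integer(rowSums(items))
    } else {
      phenotype <- 18 + 4 * latent
    }

    if (config$miss_rate > 0) {
      nm <- rbinom(1, n * V, config$miss_rate)
      dosages[sample.int(n * V, nm)] <- NA_real_
    }

    variants <- data.frame(
      chrom = chrom, pos = pos, ref = alleles[, 1], alt = alleles[, 2],
      maf = maf, info_r2 = rep(1, V),
      call_rate = colMeans(!is.na(dosages)),
      stringsAsFactors = FALSE
    )
    variants$id <- variant_ids(variants)
    colnames(dosages) <- variants$id
    rownames(dosages) <- sprintf("ind%04d", seq_len(n))

    structure(list(
      dosages = dosages, variants = variants, phenotype = phenotype,
      covariates = covariates, sex = sex, config = config
    ), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d individuals x %d variants (%s phenotype)\n",
              nrow(x$dosages), ncol(x$dosages), x$config$phenotype_mode))
  invisible(x)
}

#' Simulate a gene annotation and GO-style gene-set collection
#'
#' Genes get unique ids, a chromosome, and strictly increasing TSS per
#' chromosome; sets are sampled without replacement from the gene universe.
#' When `variants` is supplied, TSS positions are drawn to span the variant
#' positions on each chromosome so that nearest-TSS annotation is exercised;
#' `planted_set` adds one extra named set containing exactly the given gene
#' ids (e.g. the genes nearest to the causal variants of a simulated cohort).
#'
#' @param n_genes Number of genes in the universe.
#' @param n_sets Number of random gene sets.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param planted_set Optional character vector of gene ids to plant as an
#'   extra set named `"PLANTED"`.
#' @param seed Integer seed.
#' @param variants Optional variant `data.frame` (`chrom`, `pos`) whose
#'   chromosomes and position ranges the annotation should cover.
#' @param chroms Chromosome labels used when `variants` is `NULL`.
#' @return A list with elements `annotation` (a `data.frame` with `gene_id`,
#'   `chrom`, `tss`, `strand`) and `sets` (a [gene_set_collection()]).
#' @export
simulate_annotation_and_sets <- function(n_genes, n_sets, set_size_range,
                                         planted_set = NULL, seed = 1L,
                                         variants = NULL,
                                         chroms = as.character(1:22)) {
  if (max(set_size_range) > n_genes)
    stop("set_size_range exceeds n_genes")
  with_seed(seed, {
    if (!is.null(variants)) chroms <- unique(variants$chrom)
    gene_chrom <- sort(rep_len(seq_along(chroms), n_genes))
    ann <- data.frame(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      chrom = chroms[gene_chrom],
      tss = NA_integer_,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (ci in seq_along(chroms)) {
      idx <- which(gene_chrom == ci)
      if (!is.null(variants)) {
        vp <- variants$pos[variants$chrom == chroms[ci]]
        lo <- max(1, min(vp) - 5e4); hi <- max(vp) + 5e4
      } else {
        lo <- 1e6; hi <- 5e7
      }
      ann$tss[idx] <- sort(sample(seq(lo, hi), length(idx)))
    }
    universe <- ann$gene_id
    sizes <- sample(seq(set_size_range[1], set_size_range[2]),
                    n_sets, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(universe, s))
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    desc <- setNames(sprintf("random set %d", seq_len(n_sets)), names(sets))
    if (!is.null(planted_set)) {
      stopifnot(all(planted_set %in% universe))
      sets$PLANTED <- planted_set
      desc["PLANTED"] <- "planted enriched set"
    }
    list(annotation = ann,
         sets = gene_set_collection(sets, universe, desc))
  })
}

#' Simulate base (external) GWAS summary statistics
#'
#' Stands in for the large external discovery GWAS from which polygenic-score
#' weights are taken. True standardized per-variant effects are drawn so that
#' the implied additive genetic variance equals `h2`; when the cohort records
#' planted causal variants, the true effects are concentrated on those
#' variants with signs matching the planted effects (shared architecture),
#' otherwise an infinitesimal model is used. Reported betas carry sampling
#' noise at base-study size `n_base`.
#'
#' @param cohort A [simulate_cohort()] result (supplies variants and MAFs).
#' @param h2 Additive genetic variance of the base trait, in `[0, 1)`.
#' @param seed Integer seed.
#' @param n_base Base-study sample size governing the sampling noise.
#' @return A `data.frame` of class `base_sumstats` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `effect_allele`, `beta`, `se`, `p`, `maf`, `n`.
#' @export
simulate_base_gwas <- function(cohort, h2, seed = 1L, n_base = 1e5) {
  if (h2 < 0 || h2 >= 1) stop("h2 must be in [0, 1)")
  with_seed(seed, {
    v <- cohort$variants
    V <- nrow(v)
    b <- numeric(V)
    causal <- cohort$config$causal_spec
    if (h2 > 0) {
      if (!is.null(causal) && nrow(causal) > 0) {
        w <- sqrt(causal$pve)
        b[causal$index] <- w * sqrt(h2 / sum(w^2))
      } else {
        b <- rnorm(V, sd = sqrt(h2 / V))
      }
    }
    se_std <- 1 / sqrt(n_base)
    bhat_std <- b + rnorm(V, sd = se_std)
    sd_g <- sqrt(2 * v$maf * (1 - v$maf))
    beta <- bhat_std / sd_g
    se <- se_std / sd_g
    z <- bhat_std / se_std
    out <- data.frame(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      effect_allele = v$alt, beta = beta, se = se,
      p = 2 * pnorm(-abs(z)), maf = v$maf, n = n_base,
      stringsAsFactors = FALSE
    )
    class(out) <- c("base_sumstats", "data.frame")
    out
  })
}
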