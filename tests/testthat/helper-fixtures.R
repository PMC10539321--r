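# Hand-built fixtures and independent oracles used across test files.
# Oracles are deliberately naive (direct enumeration, brute force) and share
# no code with the implementation they check.

make_cohort <- function(dosages, phenotype, covariates = NULL, sex = NULL,
                        chrom = NULL, maf = NULL, info_r2 = NULL,
                        causal_spec = data.frame(index = integer(),
                                                 pve = numeric())) {
  n <- nrow(dosages); V <- ncol(dosages)
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(n))
  if (is.null(sex)) sex <- factor(rep("female", n),
                                  levels = c("female", "male"))
  if (is.null(chrom)) chrom <- rep("1", V)
  af <- colMeans(dosages, na.rm = TRUE) / 2
  variants <- data.frame(
    chrom = chrom, pos = seq_len(V) * 1000L,
    ref = rep("A", V), alt = rep("G", V),
    maf = if (is.null(maf)) pmin(af, 1 - af) else maf,
    info_r2 = if (is.null(info_r2)) rep(1, V) else info_r2,
    call_rate = colMeans(!is.na(dosages)),
    stringsAsFactors = FALSE
  )
  variants$id <- paste(variants$chrom, variants$pos, variants$ref,
                       variants$alt, sep = ":")
  colnames(dosages) <- variants$id
  rownames(dosages) <- sprintf("ind%04d", seq_len(n))
  cfg <- sim_config(n_individuals = n, n_variants = V, n_blocks = 1,
                    causal_spec = causal_spec, seed = 0L)
  structure(list(dosages = dosages, variants = variants,
                 phenotype = phenotype, covariates = covariates, sex = sex,
                 config = cfg), class = "cohort")
}

# Exact HWE oracle: direct factorial enumeration over heterozygote counts.
hwe_oracle <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  na <- het + 2 * hom_alt
  nm <- min(na, 2 * n - na)
  if (nm == 0) return(1)
  probs <- c()
  hs <- c()
  for (h in 0:nm) {
    if ((nm - h) %% 2 != 0) next
    hm <- (nm - h) / 2
    hM <- n - h - hm
    if (hM < 0) next
    pr <- factorial(n) / (factorial(hM) * factorial(h) * factorial(hm)) *
      2^h * factorial(nm) * factorial(2 * n - nm) / factorial(2 * n)
    probs <- c(probs, pr); hs <- c(hs, h)
  }
  probs <- probs / sum(probs)
  obs <- probs[hs == het]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# Brute-force maximum independent set size on a small relatedness graph.
max_independent_set_size <- function(adj) {
  n <- nrow(adj)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(members) <= best) next
    ok <- TRUE
    if (length(members) > 1) {
      pairs <- utils::combn(members, 2)
      ok <- !any(adj[t(pairs)])
    }
    if (ok) best <- length(members)
  }
  best
}

# Independent re-simulation of the greedy clumping definition.
clump_oracle <- function(stats, r2mat, window_kb, p_threshold) {
  stats <- stats[stats$p <= p_threshold, , drop = FALSE]
  remaining <- stats[order(stats$p, stats$chrom, stats$pos), , drop = FALSE]
  kept <- remaining[0, ]
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- rbind(kept, idx)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) > 0) {
      same <- remaining$chrom == idx$chrom &
        abs(remaining$pos - idx$pos) <= window_kb * 1000
      prune <- same & r2mat[idx$vid, remaining$vid] >= attr(r2mat, "thr")
      remaining <- remaining[!prune, , drop = FALSE]
    }
  }
  kept[order(kept$chrom, kept$pos), , drop = FALSE]
}

# Upper-tail hypergeometric by explicit enumeration of the attainable
# overlap counts.
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(K, n)
  pr <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pr[ks >= k])
}
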