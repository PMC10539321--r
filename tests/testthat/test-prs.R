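make_stats <- function(chrom, pos, p) {
  data.frame(chrom = chrom, pos = pos,
             ref = "A", alt = "G", p = p, stringsAsFactors = FALSE)
}

r2_matrix <- function(stats, r2_pairs = list()) {
  ids <- paste(stats$chrom, stats$pos, stats$ref, stats$alt, sep = ":")
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  for (pr in r2_pairs) m[pr[[1]], pr[[2]]] <- m[pr[[2]], pr[[1]]] <- pr[[3]]
  m
}

test_that("independent variants all survive clumping", {
  st <- make_stats("1", c(1e5, 2e5, 3e5), c(1e-8, 1e-6, 1e-4))
  m <- r2_matrix(st)
  out <- ld_clump(st, m, clump_params())
  expect_equal(nrow(out), 3)
})

test_that("a correlated neighbour of the index variant is pruned", {
  st <- make_stats("1", c(1e5, 1.5e5, 2e5), c(1e-8, 1e-6, 1e-4))
  m <- r2_matrix(st, list(list(1, 2, 0.5)))
  out <- ld_clump(st, m, clump_params(r2_threshold = 0.1))
  expect_equal(out$pos, c(1e5, 2e5))
})

test_that("correlated variants beyond the window are both retained", {
  st <- make_stats("1", c(1e5, 1e5 + 3e5), c(1e-8, 1e-6))
  m <- r2_matrix(st, list(list(1, 2, 0.9)))
  out <- ld_clump(st, m, clump_params(r2_threshold = 0.1, window_kb = 250))
  expect_equal(nrow(out), 2)
})

test_that("clumping is invariant to input row order and leaves no close pair", {
  set.seed(20)
  V <- 30
  st <- make_stats(sample(c("1", "2"), V, replace = TRUE),
                   sample(seq(1e5, 2e6, by = 1e4), V), runif(V)^3)
  D <- matrix(rbinom(200 * V, 2, 0.3), 200, V)
  for (j in seq(2, V, by = 3)) D[, j] <- D[, j - 1]  # plant perfect LD
  colnames(D) <- paste(st$chrom, st$pos, st$ref, st$alt, sep = ":")
  params <- clump_params(r2_threshold = 0.2, window_kb = 500)
  ref <- ld_clump(st, D, params)
  for (s in 1:50) {
    set.seed(s)
    shuffled <- st[sample(nrow(st)), ]
    expect_equal(ld_clump(shuffled, D, params), ref,
                 ignore_attr = TRUE)
  }
  # post-hoc audit: no retained pair within window with r2 >= threshold
  ids <- paste(ref$chrom, ref$pos, ref$ref, ref$alt, sep = ":")
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    if (ref$chrom[i] == ref$chrom[j] &&
        abs(ref$pos[i] - ref$pos[j]) <= 5e5) {
      expect_lt(cor(D[, ids[i]], D[, ids[j]])^2, 0.2)
    }
  }
})

test_that("greedy clumping matches an independent reimplementation", {
  for (s in 1:20) {
    set.seed(100 + s)
    V <- 12
    st <- make_stats("1", sort(sample(seq(1e5, 1e6, by = 1e4), V)),
                     runif(V))
    m <- diag(V)
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    vals <- ifelse(runif(nrow(pairs)) < 0.3, runif(nrow(pairs), 0.2, 1), 0)
    m[pairs] <- vals; m <- pmax(m, t(m))
    ids <- paste(st$chrom, st$pos, st$ref, st$alt, sep = ":")
    dimnames(m) <- list(ids, ids)
    params <- clump_params(r2_threshold = 0.3, window_kb = 200,
                           p_threshold = 0.8)
    got <- ld_clump(st, m, params)
    oracle_in <- st; oracle_in$vid <- ids
    m2 <- m; attr(m2, "thr") <- 0.3
    want <- clump_oracle(oracle_in, m2, 200, 0.8)
    expect_equal(got$pos, want$pos)
  }
})

test_that("absent and non-passing variants are dropped with warnings", {
  st <- make_stats("1", c(1e5, 2e5), c(1e-8, 1e-6))
  m <- r2_matrix(st[1, , drop = FALSE])
  expect_warning(out <- ld_clump(st, m, clump_params()), "absent")
  expect_equal(nrow(out), 1)
  expect_warning(ld_clump(st[0, ], m, clump_params()), "empty")
})

test_that("scores follow the hand-computed weighted sum and centring", {
  d <- rbind(c(0, 1, 2), c(2, 1, 0))
  ch <- make_cohort(d, c(1, 2))
  model <- data.frame(chrom = "1", pos = c(1000L, 2000L, 3000L),
                      ref = "A", alt = "G", effect_allele = "G",
                      weight = c(0.5, -1, 0.25))
  sc <- build_score(model, ch)
  expect_equal(unname(sc$scores), c(-0.25, 0.25))
  expect_equal(sum(sc$scores), 0, tolerance = 1e-10)

  zero <- build_score(transform(model, weight = 0), ch)
  expect_equal(unname(zero$scores), c(0, 0))
})

test_that("effect alleles on the reference strand flip the dosage", {
  d <- rbind(c(0, 2), c(2, 0), c(1, 1))
  ch <- make_cohort(d, 1:3)
  model <- data.frame(chrom = "1", pos = c(1000L, 2000L), ref = "A",
                      alt = "G", effect_allele = c("G", "A"),
                      weight = c(1, 1))
  sc <- build_score(model, ch)
  raw <- d[, 1] * 1 + (2 - d[, 2]) * 1
  expect_equal(unname(sc$scores), raw - mean(raw))
})

test_that("ambiguous and unmatched variants are dropped; none left errors", {
  d <- cbind(rbinom(10, 2, 0.4), rbinom(10, 2, 0.4))
  ch <- make_cohort(d, rnorm(10))
  ch$variants$ref <- c("A", "A")
  ch$variants$alt <- c("T", "G")  # first is strand-ambiguous
  model <- data.frame(chrom = "1", pos = c(1000L, 2000L), ref = "A",
                      alt = c("T", "G"), effect_allele = c("T", "G"),
                      weight = c(1, 1))
  expect_warning(sc <- build_score(model, ch), "strand-ambiguous")
  expect_equal(sc$n_variants_used, 1)

  off <- transform(model, pos = pos + 5L)
  expect_error(suppressWarnings(build_score(off, ch)), "no overlapping")
})

test_that("missing dosages contribute the mean dosage times the weight", {
  d <- rbind(c(0, 1), c(2, NA), c(1, 1))
  ch <- make_cohort(d, 1:3)
  model <- data.frame(chrom = "1", pos = c(1000L, 2000L), ref = "A",
                      alt = "G", effect_allele = "G", weight = c(1, 2))
  sc <- build_score(model, ch)
  d_imp <- d; d_imp[2, 2] <- 1
  raw <- d_imp %*% c(1, 2)
  expect_equal(unname(sc$scores), as.numeric(raw - mean(raw)))
})

test_that("score association reports the family Bonferroni level", {
  set.seed(30)
  d <- matrix(rbinom(400, 2, 0.3), 100, 4)
  ch <- make_cohort(d, rnorm(100) + 0.5 * d[, 1])
  sc <- rnorm(100)
  res <- associate_score(sc, ch, n_scores_in_family = 5)
  expect_equal(res$bonferroni_alpha, 0.01)
  expect_error(associate_score(rep(1, 100), ch), "constant")

  perfect <- associate_score(ch$phenotype, ch)
  expect_equal(perfect$beta, 1, tolerance = 1e-10)
  expect_lt(perfect$p, 1e-300)
})

test_that("a shared-architecture base GWAS yields positively associated scores", {
  hits <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_individuals = 1000, n_variants = 120, n_blocks = 12,
                      rho = 0.5, phenotype_mode = "continuous",
                      causal_spec = data.frame(index = c(15L, 55L, 95L),
                                               pve = c(0.05, 0.05, 0.05)),
                      seed = 1000 + s)
    ch <- simulate_cohort(cfg)
    base <- simulate_base_gwas(ch, h2 = 0.3, seed = 2000 + s)
    clumped <- ld_clump(base, ch$dosages,
                        clump_params(r2_threshold = 0.2, window_kb = 250,
                                     p_threshold = 1e-4))
    if (nrow(clumped) == 0) next
    model <- data.frame(chrom = clumped$chrom, pos = clumped$pos,
                        ref = clumped$ref, alt = clumped$alt,
                        effect_allele = clumped$effect_allele,
                        weight = clumped$beta)
    sc <- suppressWarnings(build_score(model, ch))
    res <- associate_score(sc$scores, ch)
    if (res$beta > 0) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})
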