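ann2 <- data.frame(gene_id = c("GA", "GB"), chrom = c("1", "1"),
                   tss = c(100L, 500L), strand = c("+", "-"),
                   stringsAsFactors = FALSE)

assoc_row <- function(pos, p, chrom = "1") {
  data.frame(chrom = chrom, pos = pos, p = p, stringsAsFactors = FALSE)
}

test_that("variants map to the nearest TSS with deterministic tie-breaks", {
  # exactly at a TSS
  m <- nearest_tss_map(assoc_row(500, 1e-5), 5e-4, ann2)
  expect_equal(m$genes, "GB")
  # 250 is 150 from GA, 250 from GB
  m2 <- nearest_tss_map(assoc_row(250, 1e-5), 5e-4, ann2)
  expect_equal(m2$genes, "GA")
  # equidistant: smaller TSS wins
  m3 <- nearest_tss_map(assoc_row(300, 1e-5), 5e-4, ann2)
  expect_equal(m3$genes, "GA")
  # equal TSS: lexicographically smaller gene id wins
  ann_dup <- data.frame(gene_id = c("GZ", "GC"), chrom = "1",
                        tss = c(100L, 100L), strand = "+")
  m4 <- nearest_tss_map(assoc_row(90, 1e-5), 5e-4, ann_dup)
  expect_equal(m4$genes, "GC")
  # above-threshold variants are not selected
  m5 <- nearest_tss_map(assoc_row(c(250, 490), c(1e-5, 0.1)), 5e-4, ann2)
  expect_equal(nrow(m5$map), 1)
})

test_that("genes hit by several variants count once", {
  m <- nearest_tss_map(assoc_row(c(90, 110, 480), rep(1e-5, 3)), 5e-4, ann2)
  expect_equal(m$genes, c("GA", "GB"))
})

test_that("selected variants on unannotated chromosomes warn, not fail", {
  expect_warning(
    m <- nearest_tss_map(assoc_row(100, 1e-5, chrom = "7"), 5e-4, ann2),
    "no annotated gene")
  expect_equal(length(m$genes), 0)
  expect_equal(nrow(m$unassigned), 1)
})

test_that("hypergeometric enrichment matches closed-form values", {
  sets <- gene_set_collection(
    list(S = c("g1", "g2", "g3"), E = c("g9", "g10")),
    universe = paste0("g", 1:10))
  res <- hypergeom_enrichment(c("g1", "g2", "g3", "g4", "g5"), sets)
  s <- res[res$set_id == "S", ]
  expect_equal(s$k, 3)
  expect_equal(s$p_hyper, 21 / 252, tolerance = 1e-12)
  expect_equal(s$fold, (3 / 5) / (3 / 10))
  # zero overlap: fold 0, upper tail from zero is 1
  e <- res[res$set_id == "E", ]
  expect_equal(e$k, 0)
  expect_equal(e$fold, 0)
  expect_equal(e$p_hyper, 1)
})

test_that("enrichment warns on out-of-universe genes and errors on n = 0", {
  sets <- gene_set_collection(list(S = c("g1", "g2")),
                              universe = paste0("g", 1:5))
  expect_warning(res <- hypergeom_enrichment(c("g1", "zz"), sets),
                 "outside the universe")
  expect_equal(res$n, 1)
  expect_error(suppressWarnings(hypergeom_enrichment("zz", sets)),
               "no selected genes")
  expect_error(gene_set_collection(list(S = "bad"), universe = "g1"),
               "outside the universe")
})

test_that("hypergeometric tail equals enumeration for every N <= 25", {
  max_p_diff <- 0
  max_fold_diff <- 0
  for (N in 2:25) {
    universe <- paste0("g", 1:N)
    for (K in 1:(N - 1)) {
      sets <- gene_set_collection(list(S = universe[1:K]), universe)
      for (n in 1:(N - 1)) {
        for (k in max(0, n - (N - K)):min(K, n)) {
          # selection with exactly k members inside the set
          sel <- c(universe[seq_len(k)], universe[K + seq_len(n - k)])
          res <- hypergeom_enrichment(sel, sets)
          max_p_diff <- max(max_p_diff,
                            abs(res$p_hyper - hyper_tail_oracle(k, K, n, N)))
          max_fold_diff <- max(max_fold_diff,
                               abs(res$fold * (res$K / res$N) * res$n - res$k))
        }
      }
    }
  }
  expect_lt(max_p_diff, 1e-12)
  expect_lt(max_fold_diff, 1e-12)
})

test_that("permutation p-values match enumeration of the recorded shuffles", {
  # 4 variants, 2 genes; geometry: variants 1-2 -> GA, 3-4 -> GB
  ann <- data.frame(gene_id = c("GA", "GB"), chrom = "1",
                    tss = c(100L, 4000L), strand = "+")
  assoc <- data.frame(chrom = "1", pos = c(90, 110, 3990, 4010),
                      p = c(1e-6, 0.5, 0.6, 0.7))
  sets <- gene_set_collection(list(S = "GA"),
                              universe = c("GA", "GB", "GC", "GD"))
  B <- 4; seed <- 99; thr <- 1e-3
  res <- permutation_calibrate(assoc, thr, ann, sets, B = B, seed = seed)

  # replay the same shuffle stream and recompute each statistic naively
  gene_of <- c("GA", "GA", "GB", "GB")
  stat <- function(pv) {
    genes <- unique(gene_of[pv <= thr])
    n <- length(genes)
    if (n == 0) return(1)
    hyper_tail_oracle(sum(genes == "GA"), 1, n, 4)
  }
  obs <- stat(assoc$p)
  set.seed(seed)
  perm <- replicate(B, stat(sample(assoc$p)))
  expected <- (sum(perm <= obs) + 1) / (B + 1)
  expect_equal(res$p_perm, expected)
})

test_that("permutation p hits the floor when the observation beats every shuffle", {
  # a selected variant set that covers a whole planted set can only be
  # matched by a permutation re-selecting the same positions
  set.seed(7)
  n_genes <- 300
  ann <- data.frame(gene_id = sprintf("G%03d", 1:n_genes), chrom = "1",
                    tss = seq(1000L, by = 5000L, length.out = n_genes),
                    strand = "+")
  assoc <- data.frame(chrom = "1", pos = ann$tss, p = runif(n_genes, 0.1, 1))
  hit <- 1:8
  assoc$p[hit] <- 1e-8
  sets <- gene_set_collection(list(PL = ann$gene_id[hit],
                                   RND = ann$gene_id[50:70]),
                              universe = ann$gene_id)
  res <- permutation_calibrate(assoc, 5e-4, ann, sets, B = 400, seed = 3)
  expect_equal(res$p_perm[res$set_id == "PL"], 1 / 401)
  expect_true(all(res$p_perm >= 1 / 401 & res$p_perm <= 1))
})

test_that("permutation p is 1 when the observation is never beaten", {
  ann <- data.frame(gene_id = c("GA", "GB"), chrom = "1",
                    tss = c(100L, 4000L), strand = "+")
  # observed selection misses the set entirely: p_hyper = 1, every
  # permutation ties it
  assoc <- data.frame(chrom = "1", pos = c(90, 110, 3990, 4010),
                      p = c(0.5, 0.5, 1e-6, 0.5))
  sets <- gene_set_collection(list(S = "GA"), universe = c("GA", "GB"))
  res <- permutation_calibrate(assoc, 1e-3, ann, sets, B = 20, seed = 1)
  expect_equal(res$p_perm, 1)
  expect_error(permutation_calibrate(assoc, 1e-3, ann, sets, B = 0), "B")
})

test_that("list overlap test reproduces exact tail probabilities", {
  uni <- paste0("g", 1:20)
  res <- list_overlap_test(paste0("g", 1:5), paste0("g", 1:8), uni)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, 56 / 15504, tolerance = 1e-12)

  disj <- list_overlap_test(paste0("g", 1:5), paste0("g", 10:12), uni)
  expect_equal(disj$overlap, 0)
  expect_equal(disj$p, 1)

  full <- list_overlap_test(uni, uni, uni)
  expect_equal(full$overlap, 20)
  expect_equal(full$p, 1)

  expect_warning(list_overlap_test(c("g1", "zz"), "g1", uni), "dropped")
  expect_error(list_overlap_test("g1", "g2", character(0)), "empty universe")
})
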