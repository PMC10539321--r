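#' Default end-to-end pipeline configuration
#'
#' Nested blocks mirroring each stage's own configuration: `sim` (cohort
#' generator), `annotation` (gene models and sets), `qc`, `assoc`, `enrich`
#' (selection threshold, permutation count), `prs` (clumping parameters,
#' base-GWAS heritability), `power`, plus the global `seed`. Every block is
#' validated by its stage's constructor before any stage runs.
#'
#' @param seed Global integer seed; per-stage substreams are derived from
#'   it.
#' @param ... Named blocks overriding the defaults (partial lists are
#'   merged).
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    sim = list(n_individuals = 324, n_variants = 1000, n_blocks = 20,
               rho = 0.8, maf_range = c(0.05, 0.5),
               causal_spec = data.frame(index = c(101L, 501L),
                                        pve = c(0.101, 0.093)),
               phenotype_mode = "bis_like", miss_rate = 0),
    annotation = list(n_genes = 200, n_sets = 20,
                      set_size_range = c(5, 30), plant_causal_set = TRUE),
    qc = list(),
    assoc = list(transform = "raw", missing = "complete"),
    enrich = list(threshold = 5e-4, B = 200),
    prs = list(h2 = 0.3, n_base = 1e5, r2_threshold = 0.1,
               window_kb = 250, p_threshold = 1e-3, n_scores_in_family = 5),
    power = list(pve = 0.12, alpha = 5e-8)
  )
  # one-level merge: block entries replace defaults wholesale (so a
  # causal_spec data.frame is swapped, never merged row-wise)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]]) &&
        !is.data.frame(over[[nm]])) {
      for (key in names(over[[nm]])) defaults[[nm]][[key]] <- over[[nm]][[key]]
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file whose top-level
#'   keys are [pipeline_config()] blocks.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$sim$causal_spec))
    cfg$sim$causal_spec <- as.data.frame(cfg$sim$causal_spec)
  do.call(pipeline_config,
          c(list(seed = cfg$seed %||% 1L),
            cfg[setdiff(names(cfg), "seed")]))
}

#' Run the full simulate -> QC -> association -> enrichment/PRS/PVE pipeline
#'
#' Stages execute in dependency order, each drawing randomness only from a
#' substream derived from the global seed. Every output file is written to
#' `out_dir` with a dialect header; a `manifest.json` records the seed, a
#' hash of the configuration, per-stage counts, and which stages completed.
#' A stage error aborts the run after writing the manifest for the stages
#' already completed.
#'
#' @param config A [pipeline_config()] (or a path accepted by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(seed = seed, config_hash = rlang::hash(unclass(config)),
                   stages = list())
  results <- list()
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      save_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), res$counts)
    results[[name]] <<- res$value
    save_manifest()
    res$value
  }

  cohort <- stage("simulate", function() {
    sc <- do.call(sim_config,
                  c(config$sim, list(seed = derive_seed(seed, "simulate"))))
    ch <- simulate_cohort(sc)
    write_cohort_vcf(ch, file.path(out_dir, "cohort.vcf.gz"),
                     field = if (config$sim$miss_rate == 0 &&
                                 all(ch$dosages == round(ch$dosages)))
                       "GT" else "DS")
    write_pheno_tsv(ch, file.path(out_dir, "phenotype.tsv"))
    list(value = ch, counts = list(n_individuals = nrow(ch$dosages),
                                   n_variants = ncol(ch$dosages)))
  })

  ann <- stage("annotation", function() {
    a <- simulate_annotation_and_sets(
      n_genes = config$annotation$n_genes,
      n_sets = config$annotation$n_sets,
      set_size_range = config$annotation$set_size_range,
      seed = derive_seed(seed, "annotation"),
      variants = cohort$variants)
    if (isTRUE(config$annotation$plant_causal_set) &&
        nrow(cohort$config$causal_spec) > 0) {
      causal <- cohort$variants[cohort$config$causal_spec$index, ,
                                drop = FALSE]
      causal$p <- 0
      planted <- nearest_tss_map(causal, 1, a$annotation)$genes
      sets <- a$sets$sets
      sets$PLANTED <- planted
      desc <- c(a$sets$descriptions, PLANTED = "planted enriched set")
      a$sets <- gene_set_collection(sets, a$sets$universe, desc)
    }
    write_gene_models_tsv(a$annotation,
                          file.path(out_dir, "gene_models.tsv"))
    write_gmt(a$sets, file.path(out_dir, "gene_sets.gmt"))
    list(value = a, counts = list(n_genes = nrow(a$annotation),
                                  n_sets = length(a$sets$sets)))
  })

  qc_res <- stage("qc", function() {
    thr <- do.call(qc_thresholds, config$qc)
    res <- apply_variant_filters(cohort, thr)
    jsonlite::write_json(
      unclass(res$report), file.path(out_dir, "qc_report.json"),
      auto_unbox = TRUE, pretty = TRUE)
    list(value = res,
         counts = list(variants_in = res$report$n_variants_in,
                       variants_out = length(res$report$retained_variants),
                       hwe_flagged = length(res$report$hwe_flagged)))
  })

  assoc_tab <- stage("assoc", function() {
    ac <- do.call(assoc_config, config$assoc)
    tab <- run_gwas(qc_res$cohort, ac)
    write_sumstats_tsv(tab, file.path(out_dir, "sumstats.tsv"))
    list(value = tab,
         counts = list(n_variants = nrow(tab),
                       n_genomewide = sum(tab$p < ac$sig_threshold)))
  })

  enrich_tab <- stage("enrich", function() {
    tab <- permutation_calibrate(
      assoc_tab, threshold = config$enrich$threshold,
      annotation = ann$annotation, sets = ann$sets,
      B = config$enrich$B, seed = derive_seed(seed, "enrich"))
    write_dialect_tsv(tab, file.path(out_dir, "enrichment.tsv"),
                      "enrichment")
    list(value = tab,
         counts = list(n_sets = nrow(tab),
                       permutations = config$enrich$B))
  })

  prs_res <- stage("prs", function() {
    base <- simulate_base_gwas(cohort, h2 = config$prs$h2,
                               seed = derive_seed(seed, "base_gwas"),
                               n_base = config$prs$n_base)
    write_sumstats_tsv(base, file.path(out_dir, "base_sumstats.tsv"))
    cp <- clump_params(config$prs$r2_threshold, config$prs$window_kb,
                       config$prs$p_threshold)
    D <- qc_res$cohort$dosages
    clumped <- ld_clump(base, D, cp)
    model <- data.frame(chrom = clumped$chrom, pos = clumped$pos,
                        ref = clumped$ref, alt = clumped$alt,
                        effect_allele = clumped$effect_allele,
                        weight = clumped$beta, stringsAsFactors = FALSE)
    sc <- suppressWarnings(build_score(model, qc_res$cohort))
    assoc <- associate_score(sc$scores, qc_res$cohort,
                             n_scores_in_family =
                               config$prs$n_scores_in_family)
    score_tab <- data.frame(individual_id = names(sc$scores),
                            score = unname(sc$scores))
    write_dialect_tsv(score_tab, file.path(out_dir, "prs_scores.tsv"),
                      "prs_scores")
    jsonlite::write_json(unclass(assoc),
                         file.path(out_dir, "prs_assoc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(value = list(model = model, scores = sc, assoc = assoc),
         counts = list(n_index_variants = nrow(model),
                       n_scored = length(sc$scores)))
  })

  pve_res <- stage("pve_power", function() {
    out <- list()
    if (nrow(cohort$config$causal_spec) > 0) {
      ids <- cohort$variants$id[cohort$config$causal_spec$index]
      ids <- intersect(ids, qc_res$cohort$variants$id)
      if (length(ids) > 0)
        out$pve <- unclass(pve_partial_r2(qc_res$cohort, NULL, ids))
    }
    out$power <- unclass(power_detect(nrow(qc_res$cohort$dosages),
                                      config$power$pve,
                                      config$power$alpha))
    jsonlite::write_json(out, file.path(out_dir, "pve_power.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(value = out, counts = list())
  })

  invisible(list(results = results, manifest = manifest,
                 out_dir = out_dir))
}
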