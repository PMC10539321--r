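# File dialects. Every table writer puts a one-line "# endogwas:<kind>"
# comment at the top so files self-declare their dialect; readers skip it.
# VCF goes through vcfR; the remaining formats are simple TSVs and GMT.

write_dialect_tsv <- function(x, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# endogwas:%s", kind), con)
  close(con); on.exit()
  data.table::fwrite(x, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

read_dialect_tsv <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  as.data.frame(data.table::fread(path, sep = "\t", skip = skip,
                                  header = TRUE))
}

#' Write a cohort's genotypes to VCF
#'
#' VCF v4.2 with chromosomes `"1".."22","X"` and 1-based positions; hard
#' calls are written as `GT` (`0/0`, `0/1`, `1/1`, male X `0`/`1`),
#' fractional dosages as a `DS` FORMAT field. The file is bgzip/gzip
#' compressed (use a `.vcf.gz` path).
#'
#' @param cohort A `cohort` object.
#' @param path Output path (`.vcf.gz`).
#' @param field `"GT"` (hard calls; requires whole-number dosages) or
#'   `"DS"` (dosages).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, field = c("DS", "GT")) {
  field <- match.arg(field)
  v <- cohort$variants
  D <- cohort$dosages
  n <- nrow(D)
  male <- cohort$sex == "male"
  if (field == "GT") {
    if (any(D != round(D), na.rm = TRUE))
      stop("GT output requires hard-call dosages")
    gt_one <- function(g, on_x, is_male) {
      if (is.na(g)) return("./.")
      if (on_x && is_male) return(if (g >= 1) "1" else "0")
      c("0/0", "0/1", "1/1")[g + 1]
    }
    gt <- matrix("", nrow(v), n)
    for (j in seq_len(nrow(v))) {
      on_x <- v$chrom[j] == "X"
      gt[j, ] <- vapply(seq_len(n), function(i)
        gt_one(D[i, j], on_x, male[i]), character(1))
    }
    fmt <- "GT"
  } else {
    gt <- t(ifelse(is.na(D), ".", format(D, trim = TRUE, digits = 10,
                                         scientific = FALSE)))
    fmt <- "DS"
  }
  colnames(gt) <- rownames(D)
  gt <- cbind(FORMAT = fmt, gt)
  fix <- cbind(CHROM = v$chrom, POS = as.character(v$pos), ID = v$id,
               REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS",
               INFO = sprintf("MAF=%.6g;INFO_R2=%.6g", v$maf, v$info_r2))
  meta <- c("##fileformat=VCFv4.2",
            "##source=endogwas",
            "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
            "##INFO=<ID=INFO_R2,Number=1,Type=Float,Description=\"Imputation quality r2\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">")
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read genotypes from VCF into dosage form
#'
#' Reads `DS` when present, otherwise `GT` (male hemizygous X calls are
#' recoded 0/2 via [encode_dosage_x()] when `sex` is supplied).
#'
#' @param path VCF path (plain or gzipped).
#' @param sex Optional per-sample sex vector (`"male"`/`"female"`) for
#'   X-chromosome hard-call recoding.
#' @return A list with `dosages` (individuals x variants) and `variants`.
#' @export
read_cohort_vcf <- function(path, sex = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, maf = get_info("MAF"), info_r2 = get_info("INFO_R2"),
    stringsAsFactors = FALSE
  )
  variants$id <- variant_ids(variants)
  fmt <- strsplit(vcf@gt[1, "FORMAT"], ":")[[1]]
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    D <- t(ds)
  } else {
    gtm <- vcfR::extract.gt(vcf, element = "GT")
    D <- matrix(NA_real_, ncol(gtm), nrow(gtm),
                dimnames = list(colnames(gtm), rownames(gtm)))
    for (j in seq_len(nrow(gtm))) {
      gts <- gtm[j, ]
      if (variants$chrom[j] == "X" && !is.null(sex)) {
        D[, j] <- suppressWarnings(
          encode_dosage_x(ifelse(is.na(gts), "./.", gts), sex))
      } else {
        a <- gsub("\\|", "/", gts)
        D[, j] <- ifelse(is.na(a) | grepl("\\.", a),
                         NA_real_,
                         vapply(strsplit(a, "/"),
                                function(al) sum(al == "1"), numeric(1)))
      }
    }
  }
  colnames(D) <- variants$id
  variants$call_rate <- colMeans(!is.na(D))
  list(dosages = D, variants = variants)
}

#' Write/read the phenotype + covariate table
#'
#' One header row, individual id in the first column, phenotype and sex
#' columns, then covariates.
#' @param cohort A `cohort` object.
#' @param path TSV path.
#' @return `path` / a `data.frame`.
#' @export
write_pheno_tsv <- function(cohort, path) {
  tab <- data.frame(individual_id = rownames(cohort$dosages),
                    phenotype = cohort$phenotype,
                    sex = as.character(cohort$sex),
                    cohort$covariates, stringsAsFactors = FALSE)
  write_dialect_tsv(tab, path, "phenotype")
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) read_dialect_tsv(path)

#' Write/read GWAS summary statistics
#'
#' Columns `chrom, pos, ref, alt, beta, se, p, n, maf` (base statistics add
#' `effect_allele`) — the shared dialect of the association, enrichment and
#' polygenic-score stages.
#' @param stats Summary-statistics `data.frame`.
#' @param path TSV path.
#' @export
write_sumstats_tsv <- function(stats, path) {
  write_dialect_tsv(stats, path, "sumstats")
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) read_dialect_tsv(path)

#' Write/read gene models (gene id, chromosome, TSS, strand)
#' @param annotation Gene annotation `data.frame`.
#' @param path TSV path.
#' @export
write_gene_models_tsv <- function(annotation, path) {
  write_dialect_tsv(annotation[, c("gene_id", "chrom", "tss", "strand")],
                    path, "gene_models")
}

#' @rdname write_gene_models_tsv
#' @export
read_gene_models_tsv <- function(path) read_dialect_tsv(path)

#' Write/read a gene-set collection as GMT
#'
#' Standard GMT lines: set id, description, then tab-separated member gene
#' ids. The universe is not part of the GMT format, so [read_gmt()] takes it
#' as an argument (defaulting to the union of members).
#' @param sets A [gene_set_collection()].
#' @param path GMT path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(id) {
    paste(c(id, sets$descriptions[[id]], sets$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param universe Background universe for the reconstructed collection.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- setNames(vapply(parts, `[[`, character(1), 2), ids)
  sets <- setNames(lapply(parts, function(x) x[-(1:2)]), ids)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, desc)
}

#' Write/read a kinship matrix as a square TSV
#'
#' Individual ids in the header row and first column.
#' @param kinship Square symmetric matrix with dimnames.
#' @param path TSV path.
#' @export
write_kinship_tsv <- function(kinship, path) {
  tab <- data.frame(individual_id = rownames(kinship),
                    as.data.frame(kinship), check.names = FALSE)
  write_dialect_tsv(tab, path, "kinship")
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  tab <- read_dialect_tsv(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
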