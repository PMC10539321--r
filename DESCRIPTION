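Package: endogwas
Title: Downstream GWAS Toolkit for Quantitative Endophenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, covariate-adjusted per-variant association,
    permutation-calibrated nearest-TSS gene-set enrichment,
    clumping-and-thresholding polygenic scores, phenotypic-variance-explained
    and power calculations for genome-wide association studies of bounded
    quantitative endophenotypes, together with a seeded synthetic
    genotype-phenotype cohort generator so every stage can be exercised and
    tested without access to real genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    rlang,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    fgsea,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
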