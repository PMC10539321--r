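---
title: "Methods and design decisions in endogwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design decisions in endogwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what each stage of the package computes, the
defaults and why they were chosen, the numerical conventions, and what the
synthetic generator does and does not emulate. It is the reference for
every decision where more than one reasonable convention exists.

## Study setting

The package targets GWAS of a *bounded quantitative endophenotype*: a trait
scored by summing a handful of ordinal questionnaire items (the motivating
example is an 8-item impulsivity scale, items scored 1–4, totals 8–32),
measured in a modestly sized clinical cohort (hundreds of individuals, not
tens of thousands). Three consequences drive the design:

1. Single variants can plausibly explain several percent of trait variance,
   so per-variant power at `alpha = 5e-8` is a meaningful quantity even at
   n ≈ 300.
2. The phenotype is integer-valued, bounded and right-skewed, so an
   inverse normal transform is offered as a sensitivity analysis alongside
   the raw-scale regression.
3. Sub-threshold signal matters: gene-set enrichment of variants at
   `p ≤ 5e-4` is a primary analysis, and because selection, annotation and
   set overlap interact with LD, the hypergeometric p-value is calibrated
   by permutation rather than trusted at face value.

## Quality control

`qc_thresholds()` encodes the defaults: variant call rate ≥ 0.90, MAF
≥ 0.01, imputation info r² > 0.4, Hardy–Weinberg exact-test p < 1e-4,
kinship < 0.088, individual call rate ≥ 0.90. Filters are applied in a
fixed order (call rate, then MAF, then info), with each variant counted
against the first filter it fails, so the report's removal tallies are
exclusive and sum correctly.

Two deliberate choices:

- **HWE failures are flagged, not removed.** In a patient cohort with
  planted strong effects, HWE departures can be signal as well as artefact;
  the flag is carried in the QC report so downstream consumers can decide.
  The test itself is the exact conditional test: given the minor-allele
  count, the probability of each heterozygote count of the same parity is
  computed in log space via `lfactorial`, and the p-value sums all
  configurations no more probable than the observed one (with a relative
  tolerance of 1e-10 to make the "equally probable" comparison robust to
  floating point). No CRAN/Bioconductor package exposes exactly this
  primitive for dosage-free genotype counts, so it is implemented directly
  and tested exhaustively against a direct-factorial oracle for all
  configurations up to n = 20.
- **Unrelated-subset selection is greedy, not optimal.** From the kinship
  graph thresholded at 0.088, the individual with the most remaining
  related pairs is removed repeatedly until no pairs remain (ties broken by
  the latest index, i.e. later samples are dropped first). Maximum
  independent set is NP-hard; on realistic kinship graphs, which are sparse
  unions of small family cliques, the greedy answer is optimal or within
  one of optimal, which the tests check against a brute-force oracle on
  random 8-node graphs.

The inverse normal transform is the Blom variant: for m non-missing values
with average ranks r, `qnorm((r - 3/8) / (m - 2*3/8 + 1))`. The 3/8 offset
is the standard choice for approximating normal order statistics; ties
share the average rank, and missing values stay missing.

## Association model

For each variant, the trait is regressed on alt-allele dosage plus
covariates with an intercept, and the dosage coefficient is tested with a
t-distribution on `n - p - 1` degrees of freedom. Two missing-dosage
policies exist: per-variant complete cases (default) or mean imputation.
When no values are missing (or means are imputed), all variants share the
same covariate projection, so the scan uses the Frisch–Waugh–Lovell
identity — residualize the trait and every dosage column on the covariates
once, then each per-variant fit is a univariate regression of residuals.
This is algebraically exact (tested to 1e-10 against `lm()`), not an
approximation, and makes a 5000-variant scan essentially instantaneous.

On the non-pseudoautosomal X, hemizygous males are coded 0/2 — the single
allele counted twice — which is the dosage convention consistent with
X-inactivation in females. `encode_dosage_x()` applies it when parsing GT
fields, and `run_gwas()` doubles male dosages ≤ 1 on X when
`x_male_coding = TRUE`; a male heterozygous GT call on X is an error, not
silently recoded. Monomorphic variants get `beta = NA`, `p = 1` rather
than a spurious zero-variance fit, and p-values are clamped at
`.Machine$double.xmin` so downstream `log` and ranking never see exact
zeros.

## Gene-set enrichment

Variants with `p <= 5e-4` are mapped to the gene with the nearest
transcription start site. Ties in distance are broken toward the smaller
TSS coordinate, and genes sharing a TSS toward the lexicographically
smaller gene id — arbitrary but fixed, so the map is deterministic. The
mapped genes are deduplicated; the resulting unique-gene list of size n is
intersected with each set (k of K members, universe N) and tested with the
one-sided hypergeometric tail
`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`. Fold enrichment is
`(k/n) / (K/N)`.

The calibration shuffles the **p-value column** of the association table
B = 2000 times; geometry (positions, annotation, sets) is fixed, so the
null preserves LD structure and the selection mechanism while breaking the
p-to-position link. For each shuffle the threshold, nearest-TSS map,
dedup and hypergeometric test are re-applied; the permutation p-value is
`(b + 1) / (B + 1)` with b the number of shuffles whose statistic is at
least as extreme as observed (compared on the hypergeometric p with a
1e-12 absolute slack). The pseudo-count makes the smallest reportable
value `1/(B + 1)` = 1/2001 ≈ 0.0005 at the default B — a floor, not an
estimate of zero.

One behaviour worth knowing: because each shuffle re-selects and re-maps,
the permuted unique-gene count n varies across shuffles. A set can
therefore receive a small permutation p with a large observed
hypergeometric p when the observed selection is unusually LD-clustered
(small n). That is a genuine property of the shuffle-and-reselect null,
not a bug, and is why the calibrated p, not the raw hypergeometric p, is
the reported quantity.

`list_overlap_test()` applies the same hypergeometric tail to the overlap
of two fixed gene lists in a common universe.

## Polygenic scores

Clumping-and-thresholding: candidate variants below the p threshold are
ranked by p (ties by chromosome, then position); the best remaining variant
indexes a clump and removes every variant within the physical window whose
r² with it meets the threshold, and so on. Defaults r² ≥ 0.1 within
±250 kb mirror common practice. The scan order is canonicalised before
clumping, so input row order never changes the result (verified by
50-shuffle invariance tests and an independent re-implementation oracle).

Scoring reconciles alleles between the external model and the cohort:
weights are flipped when the model's effect allele is the cohort's
reference allele; strand-ambiguous variants (A/T, G/C) are dropped because
strand cannot be resolved from alleles alone; allele mismatches are
dropped with a warning. Missing dosages are mean-imputed per variant and
scores are mean-centred. Score–trait association reuses the covariate
model, and the significance level is Bonferroni-corrected for the declared
family of scores (five base thresholds → 0.05/5 = 0.01).

## PVE and power

Phenotypic variance explained by a variant (or set of variants) is the
partial r²: `(rss_base - rss_full) / rss_base`, where the base model has
covariates only and the full model adds the variant dosages. The estimate
is clamped to [0, 1].

Analytic power uses the 1-df noncentral chi-square:
`power = P(chisq_1(ncp) > qchisq(1 - alpha, 1))`. Two noncentrality
conventions appear in the literature; both are implemented:

- `ncp = "pve_ratio"` (default): `λ = n * pve / (1 - pve)`, the exact
  noncentrality of the partial-F/likelihood-ratio statistic. At n = 324,
  pve = 0.12, alpha = 5e-8 this gives power 0.884.
- `ncp = "n_pve"`: `λ = n * pve`, a common approximation that is slightly
  conservative (≈ 0.78 at the same point).

The default was chosen because it is the exact expression for the model
actually fitted; the tests verify both orderings and check the default
against a 100 000-replicate Monte-Carlo simulation.

## Synthetic generator

`simulate_cohort()` builds genotypes as two latent-Gaussian haplotypes per
individual: within each LD block the latent process is AR(1) with
correlation `rho` (default 0.8), and a variant's haplotype allele is 1 when
the latent value exceeds `qnorm(maf)`. Dosage is the haplotype sum. Blocks
are assigned cyclically to chromosomes 1–22 (optionally one X block, with
males drawn as 0/2). The threshold construction means the *genotype*
correlation of adjacent variants is below `rho` (attenuation through the
thresholds); the tests pin the implied correlation with a
numerical-integration oracle rather than asserting `rho` itself.

Causal variants are planted on standardized genotypes with effect
`sqrt(pve)` against unit residual variance, so the planted PVE is the
population partial r². Covariates (sex, age, batch, seizure burden,
ancestry axes) enter the phenotype with fixed small effects so that
covariate adjustment is non-trivial. The `bis_like` phenotype mode
emulates the questionnaire: the latent trait loads equally on 8 items,
each item is cut at `qnorm(c(0.5, 0.8, 0.95))` into scores 1–4, and the
sum gives a right-skewed integer total in 8–32. `simulate_base_gwas()`
fabricates external summary statistics whose effects concentrate on the
cohort's causal variants (shared architecture) scaled to a target
heritability, for exercising the PRS stage.

What the generator does **not** emulate: realistic recombination maps or
MAF spectra, population stratification beyond linear ancestry axes,
genotyping-batch artefacts, imputation error correlated with MAF, or
ascertainment of the clinical cohort. It is a testbed with controllable
truth, not a population-genetics simulator.

## Reproducibility conventions

All randomness flows through `with_seed()`, which saves and restores
`.Random.seed`, so library calls never perturb a caller's RNG state.
Multi-stage procedures derive independent substreams with
`derive_seed(seed, label)` (a Lehmer-style mix of the seed and a string
hash, reduced mod 2³¹−1), so inserting or reordering stages does not shift
downstream streams. `run_pipeline()` writes a `manifest.json` containing
the seed, a hash of the full configuration, and per-stage counts; two runs
with the same configuration produce byte-identical outputs.

File formats are standard: VCF v4.2 (GT for hard calls, DS for fractional
dosages) via `vcfR`; tab-separated tables with a one-line
`# endogwas:<kind>` dialect header; GMT for gene sets (read/written
directly so descriptions survive; cross-checked against
`fgsea::gmtPathways`); YAML or JSON pipeline configurations.

## Default problem sizes in the tests and scripts

The sizes used by the package's own tests and by `scripts/acceptance.R`
(e.g. a 2000 × 600 cohort with eight spread causal variants, a 1000-gene
universe, B = 2000 shuffles; 200-seed replications for estimator-recovery
and calibration-uniformity checks) are the package's own choices, picked
to make the statistical assertions well-powered while keeping the full
suite around a minute of runtime. They are not tuned to any particular
dataset.

## Limitations

- The association model is OLS; no mixed-model correction for residual
  relatedness or stratification beyond supplied covariates.
- The greedy unrelated-subset selection is not guaranteed optimal on dense
  kinship graphs.
- Permutation calibration shuffles p-values as an exchangeable column;
  with strong genome-wide inflation the null would inherit it.
- The clumping r² is computed from cohort dosages (or a supplied matrix),
  not an external reference panel.
- Power formulas assume the 1-df additive test; no dominance or
  interaction terms.
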