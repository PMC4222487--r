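---
title: "Methods: candidate-gene BMI association and the weighted genetic risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene BMI association and the weighted genetic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgrs)
```

## The study design this package implements

`wgrs` implements a two-cohort candidate-gene analysis of body-mass index
(BMI, kg/m²). The design is the classical one for obesity genetics before
large meta-consortia: a panel of tag SNPs in known obesity loci (*FTO*,
*MC4R*, *MTCH2*, *NEGR1*, *BDNF*, ... — 26 tags in 23 loci, bundled as
`snp_panel()`) is typed in two general-population cohorts — here a rural
southern Spanish cohort ("pizarra", n = 869, BMI 28.6 ± 5.2) and an urban
cohort ("hortega", n = 1425, BMI 26.4 ± 4.2, `cohort_reference()`) — and
analysed per cohort, pooled, and as a two-study meta-analysis, before the
nominally positive signals are combined into a weighted genetic risk score
(wGRS).

Every stage is a plain, documented function; `run_pipeline()` chains them in
the study's order: QC → association → meta-analysis → wGRS.

## Genotype quality control

Individuals with a genotyping call rate below 95% are removed first; SNPs
are then dropped if monomorphic, call rate < 95%, minor allele frequency
(MAF) < 1%, or Hardy–Weinberg equilibrium (HWE) exact p < 0.001. The HWE
test (`hwe_exact_test()`) is the exact conditional test — summing the
probabilities of all heterozygote counts, given the observed allele totals,
that are no more probable than the observed table. The exact form is the
standard GWAS-toolchain choice; the asymptotic chi-square misbehaves exactly
where QC matters (low minor-allele counts). Filtering individuals before
SNPs matters because a few badly-typed samples can otherwise drag many SNPs
below the SNP call-rate threshold; the order makes the filter idempotent.

Two conventions had to be fixed where the design was genuinely open:

* the "controls" subset for the secondary HWE column is the **non-obese**
  (BMI < 30) individuals — in an obesity study, obese subjects are the
  "cases" and genotyping artefacts are screened in the remainder;
* HWE at the X-linked SNP (rs3813929, *HTR2C*) is computed in **females
  only**, because hemizygous males have no heterozygote class.

## Additive association model

For each SNP, `additive_regression()` fits ordinary least squares of BMI on
the 0/1/2 count of the effect allele, adjusted for age and sex (optionally a
type-2-diabetes flag), on complete cases only — which is why the per-SNP N
varies. P-values are two-sided from the t distribution with residual
degrees of freedom (cohort sizes are finite; the normal approximation is
reserved for the meta-analysis stage, below). The pooled analysis adds a
cohort indicator by default; the study reported that adjusting for cohort
left conclusions unchanged, and the flag `pooled_cohort_covariate` lets
either variant be run. Multiple testing is controlled by Bonferroni over the
26 independent tag tests: 0.05/26 = **0.00192**.

Hemizygous males at X-linked SNPs are coded 0/1 by default (a per-allele
effect on the male scale), with a `x_male_coding = "0-2"` switch; the
source analyses do not state the coding, and the default keeps "per allele
copy" literally true.

`snp_interaction()` adds a multiplicative `g1 × g2` term and reports the
product-term estimate plus adjusted 3×3 joint-genotype cell means (empty
cells are `NA`, the fit proceeds).

## LD, haplotypes, blocks and tags

LD is measured with r², computed from EM haplotype frequencies on shared
complete cases. `em_haplotype_frequencies()` is a standard
expectation–maximization over latent diplotypes, restricted to blocks of ≤ 8
SNPs (2⁸ haplotypes — the largest per-gene panel here, *FTO*, has 8 SNPs).
Numerical contract: uniform initialization, L1 convergence tolerance 1e-8,
1000-iteration cap with a warning flag (not an error) on non-convergence,
and an assertion that the observed-data log-likelihood never decreases. A
missing genotype expands an individual's compatible-diplotype set over that
site rather than dropping the individual; individuals missing more than half
the block are excluded from estimation and get `NA` dosages.

Blocks are maximal runs of consecutive, position-ordered SNPs with all
pairwise r² ≥ 0.8 — a deliberately simple threshold-run rule rather than the
D′-confidence-interval method of classical GUI tools, because the analysis
this package reproduces characterized its *FTO* block purely as "r² > 0.8".
Tags are selected greedily (repeatedly take the SNP covering the most
untagged SNPs at r² ≥ threshold, ties to the lower position); on ≤ 8-SNP
panels the greedy count is verified in tests against exhaustive minimum set
cover. Exact reproduction of the bundled panel's historical tag flags is
not claimed; the flags mark the 26 SNPs the analyses actually used.

Haplotype association is one-vs-rest linear regression of BMI on each
common haplotype's expected dosage (frequency floor 1%), matching
per-haplotype effect reporting.

## Two-cohort meta-analysis

Effect alleles are harmonized first (`align_alleles()`): a swap within the
panel's allele pair flips the sign; an effect allele outside the pair is an
irreconcilable **allele mismatch**; a swap on a strand-ambiguous (A/T, C/G)
pair cannot be distinguished from a strand difference and is excluded as
such. The bundled summary statistics reproduce the two historical
exclusions (rs4712652, rs1424233), whose panel records carry the
assay-strand pair — a synthetic but mechanistically faithful reconstruction,
flagged in the `snp_panel()` documentation.

Pooling is inverse-variance fixed-effect plus DerSimonian–Laird
random-effects, with Cochran's Q and I² = max(0, (Q−df)/Q)·100.
DerSimonian–Laird was chosen because it is the estimator of the toolchain
the original analysis used, and it reproduces the published random-effects
estimates from the published per-cohort inputs: with (0.875 ± 0.23) and
(0.1348 ± 0.15) for rs9939609, the package computes FE β = 0.3557,
DL β = 0.4844, I² = 86.2 — against printed values 0.3544, 0.4843, 86.22.
Residual differences at the third decimal trace to the inputs' 2-decimal SE
rounding, hence the package's stated reproduction tolerances (±0.01 on
betas, ±1.5 points on I²). Pooled p-values use the normal approximation,
consistent with how the printed p-values relate to the printed estimates.

## The weighted genetic risk score

Selection: the tag SNPs with a **positive beta in all three analyses** (both
cohorts and pooled). On the bundled estimates this yields exactly six SNPs:
rs9939609 and rs6499640 (*FTO*), rs17782313 (*MC4R*), rs10838738 (*MTCH2*),
rs7647305 (*ETV5*) and rs10501087 (*BDNF*).

Scoring: each individual's 0/1/2 risk-allele counts are weighted by the
effect sizes, re-scaled by the mean effect size, summed, and rounded to the
nearest integer. Conventions fixed here: weights default to the **pooled**
betas (the source does not say which effect sizes weighted its score);
rounding ties go **half away from zero**; a missing genotype contributes
twice the cohort risk-allele frequency (`grs_missing = "drop"` scores
complete cases instead). Rescaling by the mean makes the score invariant to
multiplying all weights by a constant.

Evaluation: quintiles are cut on the integer score at the 20/40/60/80th
percentiles with ties to the lower quintile (exact 20% groups are impossible
on a small integer support; groups can collapse, which is reported as a
warning). Adjusted quintile BMI means and 95% CIs come from the regression
of BMI on quintile indicators plus age and sex, evaluated at sample-mean
covariates. The score is also summarized by its Pearson correlation with
BMI and by the ROC AUC for obesity (BMI ≥ 30), computed as the Mann–Whitney
probability with ties counted half.

## The synthetic two-cohort generator

`generate_cohort()` emulates the data-generating assumptions of the
analysis model itself: genotypes are two independent allele draws per SNP
(Hardy–Weinberg proportions) — or two haplotype draws from an LD pool built
by `simulate_haplotype_pool()` — and BMI is

> intercept + 0.05·age + 0.6·[female] + Σⱼ βⱼ·gᵢⱼ + N(0, σ)

with ages normal truncated to 18–90 and sex Bernoulli. Defaults are the
study's printed conditions: cohort sizes 869/1425, the per-cohort
effect-allele frequencies and betas of the bundled summary statistics, and
intercept/σ solved so the marginal BMI mean and SD match 28.6 ± 5.2 and
26.4 ± 4.2. The age and sex effects (0.05 kg/m² per year; 0.6 kg/m²
female–male) are package choices of realistic magnitude — the calibration
sources publish only marginal summaries — and the BMI calibration absorbs
them, so downstream conclusions do not hinge on either number. Missingness
is missing-completely-at-random at ~1% per SNP plus 0.5% per individual,
inside the 0.3–5% per-SNP range of the published call rates; diabetes is an
independent Bernoulli flag at the printed prevalence (it enters the
analysis only as an optional covariate).

What the generator deliberately does **not** emulate: population
stratification or admixture, genotyping-error (non-MCAR) patterns,
age–genotype interactions, and any phenotype beyond BMI/obesity/DM2. Tests
passing on this generator therefore validate the *statistical machinery*
under the stated model, not robustness to real-data pathologies.

For the LD pool, two-SNP targets are met exactly in closed form (positive
D, with the attainable bound D²/(p_A q_A p_B q_B) reported on infeasible
requests); longer pools are first-order Markov chains on adjacent pairs, so
non-adjacent correlations decay as products of adjacent ones — adequate for
the block structures used here, and stated rather than hidden.

## Verification strategy and problem sizes

Every primitive is tested against an independent brute-force oracle on
small instances: HWE against plain-factorial enumeration, OLS against the
normal equations, EM against a 0.01-step grid search of the 2-SNP haplotype
simplex (a finer grid adds nothing but runtime), DerSimonian–Laird against
direct formula evaluation and against `metafor`, AUC against case–control
pair enumeration and against `pROC`, greedy tagging against exhaustive set
cover. Statistical properties use replicated simulation at moderate sizes
chosen to keep the default suite under a minute of heavy computation:
CI coverage of the rs9939609 effect (0.875 kg/m²) at n = 848 over 200
replicates; null type-I error over 500 replicates of a 4-SNP, n = 300
cohort; score behaviour over 25 replicates of the pooled n = 2215 cohort.

One published-derived expectation did not survive independent verification:
with the six pooled score SNPs at their printed frequencies and effect
sizes, the *strict* ordering of all five adjusted quintile means holds in
only ~40% of replicates (adjacent true gaps of ~0.2–0.3 kg/m² against
quintile-mean standard errors of ~0.22). The reproducible property at those
conditions — and what the tests assert — is the monotone *gradient*: Q5
above Q1 and a positive linear trend across quintiles (≈100% of
replicates), together with a mean incremental R² of the score for BMI below
0.01, matching the original finding that the score explains under 1% of
BMI variance.

## Known limitations

* Meta-analysis is specialized to two cohorts (the design here); no
  meta-regression or publication-bias machinery.
* The EM estimator is exponential in block width and hard-capped at 8 SNPs.
* Bit-exact reproduction of the historical meta-analysis table is
  impossible from 2-decimal rounded inputs; tolerances above are the
  contract.
* The tabular genotype dialect stores dosages only; allele pairs ride on a
  header comment, and strand information is not modelled at load time.
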