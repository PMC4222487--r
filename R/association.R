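#' Additive-model linear regression of BMI on allele dosage
#'
#' Ordinary least squares of `bmi ~ genotype + covariates` on complete cases,
#' the genotype entering as a 0/1/2 allele count (additive inheritance). The
#' reported `n` is the complete-case count, `beta` the per-allele effect in
#' kg/m2, and the two-sided p-value comes from the t distribution with the
#' residual degrees of freedom.
#'
#' @param bmi numeric outcome vector, kg/m2.
#' @param genotype allele counts (0/1/2; 0/1 for hemizygous males), `NA`
#'   missing.
#' @param covariates optional data.frame of adjustment covariates (e.g. age,
#'   sex indicator, dm2, cohort factor), row-aligned with `bmi`.
#' @param snp_id,cohort,effect_allele labels copied into the result.
#' @return one-row data.frame: `snp_id`, `cohort`, `effect_allele`, `eaf`,
#'   `n`, `beta`, `se`, `t_stat`, `p`.
#' @export
additive_regression <- function(bmi, genotype, covariates = NULL,
                                snp_id = NA_character_,
                                cohort = NA_character_,
                                effect_allele = NA_character_) {
  df <- data.frame(.bmi = bmi, .g = genotype)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(bmi))
    df <- cbind(df, covariates)
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n_par <- 2L + if (is.null(covariates)) 0L else ncol(covariates)
  if (nrow(df) < n_par + 1L)
    stopf("too few complete cases (%d) for %d parameters", nrow(df), n_par)
  if (length(unique(df$.g)) < 2L)
    stopf("degenerate predictor: genotype is constant among complete cases")
  fit <- stats::lm(.bmi ~ ., data = df)
  co <- stats::coef(fit)
  if (any(is.na(co)))
    stopf("rank error: collinear covariates (%s)",
          paste(names(co)[is.na(co)], collapse = ", "))
  sm <- summary(fit)$coefficients
  eaf <- sum(df$.g) / (2 * nrow(df))
  data.frame(
    snp_id = snp_id, cohort = cohort, effect_allele = effect_allele,
    eaf = eaf, n = nrow(df),
    beta = unname(sm[".g", 1]), se = unname(sm[".g", 2]),
    t_stat = unname(sm[".g", 3]), p = unname(sm[".g", 4]),
    stringsAsFactors = FALSE
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise type-I error level.
#' @param m number of independent tests (>= 1).
#' @return `alpha / m`. With the study defaults (0.05, 26) this is 0.00192 to
#'   three significant figures.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 26L) {
  if (m < 1) stopf("m must be >= 1")
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0,1]")
  alpha / m
}

#' SNP x SNP interaction test
#'
#' Fits `bmi ~ g1 + g2 + g1:g2 + covariates` and reports the multiplicative
#' (product-term) estimate, plus the model-adjusted mean BMI for each of the
#' 3 x 3 joint-genotype cells evaluated at sample-mean covariates. Cells with
#' no observations are reported as `NA` but do not stop the fit.
#'
#' @inheritParams additive_regression
#' @param g1,g2 allele-count vectors of the two SNPs.
#' @return list with `beta`, `se`, `t_stat`, `p` (interaction term) and
#'   `cell_means` (3x3 matrix, rows = g1 0/1/2, cols = g2 0/1/2).
#' @export
snp_interaction <- function(bmi, g1, g2, covariates = NULL) {
  df <- data.frame(.bmi = bmi, .g1 = g1, .g2 = g2)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$.g1)) < 2L || length(unique(df$.g2)) < 2L)
    stopf("degenerate predictor: a genotype is constant among complete cases")
  other <- setdiff(names(df), c(".bmi", ".g1", ".g2"))
  form <- stats::reformulate(c(".g1 * .g2", other), response = ".bmi")
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)$coefficients
  if (!".g1:.g2" %in% rownames(sm))
    stopf("rank error: interaction term is collinear")
  cell <- matrix(NA_real_, 3, 3, dimnames = list(g1 = 0:2, g2 = 0:2))
  co <- stats::coef(fit)
  cov_names <- setdiff(names(co), c("(Intercept)", ".g1", ".g2", ".g1:.g2"))
  cov_mean <- if (length(cov_names))
    colMeans(stats::model.matrix(fit))[cov_names] else NULL
  for (a in 0:2) for (b in 0:2) {
    if (!any(df$.g1 == a & df$.g2 == b)) next
    mu <- co[["(Intercept)"]] + co[[".g1"]] * a + co[[".g2"]] * b +
      co[[".g1:.g2"]] * a * b
    if (!is.null(cov_mean)) mu <- mu + sum(co[names(cov_mean)] * cov_mean)
    cell[a + 1, b + 1] <- mu
  }
  list(beta = unname(sm[".g1:.g2", 1]), se = unname(sm[".g1:.g2", 2]),
       t_stat = unname(sm[".g1:.g2", 3]), p = unname(sm[".g1:.g2", 4]),
       cell_means = cell)
}

#' Per-SNP association across cohorts and pooled
#'
#' Runs [additive_regression()] for every SNP in the (QC-passed) genotype
#' matrix: once per cohort and once pooled, each adjusted for age and sex
#' (optionally type-2 diabetes). Dosages are oriented to the panel's effect
#' allele (`allele_a1`); the pooled model includes a cohort indicator by
#' default. Bonferroni flags use `alpha / n_independent_tests` from the
#' config.
#'
#' @param genotypes a [geno_matrix()] (after [apply_qc()]).
#' @param phenotypes matching [phenotype_table()].
#' @param panel [snp_panel()]-style annotation for the SNPs.
#' @param config a [study_config()].
#' @param include_dm2 adjust additionally for the diabetes flag.
#' @return data.frame of association rows (one per SNP x analysis) with a
#'   `significant_bonferroni` flag.
#' @export
run_panel <- function(genotypes, phenotypes, panel, config = study_config(),
                      include_dm2 = FALSE) {
  ids <- rownames(genotypes$counts)
  ph <- phenotypes[match(ids, phenotypes$individual_id), ]
  if (anyNA(ph$individual_id)) stopf("phenotypes missing for some genotyped individuals")
  cohorts <- sort(unique(ph$cohort))
  analyses <- c(cohorts, if (length(cohorts) > 1L) "pooled")
  thr <- bonferroni_threshold(config$alpha, config$n_independent_tests)
  out <- list()
  for (snp in colnames(genotypes$counts)) {
    eff <- panel$allele_a1[match(snp, panel$snp_id)]
    dose <- orient_dosage(genotypes, snp, eff, panel, sex = ph$sex,
                          x_male_coding = config$x_male_coding)
    for (an in analyses) {
      sel <- if (an == "pooled") rep(TRUE, length(ids)) else ph$cohort == an
      covs <- data.frame(age = ph$age[sel],
                         sex = as.integer(ph$sex[sel] == "female"))
      if (include_dm2) covs$dm2 <- as.integer(ph$dm2[sel])
      if (an == "pooled" && config$pooled_cohort_covariate && length(cohorts) > 1L)
        covs$cohort_ind <- as.integer(factor(ph$cohort[sel], levels = cohorts)) - 1L
      row <- additive_regression(ph$bmi[sel], dose[sel], covs,
                                 snp_id = snp, cohort = an, effect_allele = eff)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  res$significant_bonferroni <- res$p < thr
  rownames(res) <- NULL
  res
}
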