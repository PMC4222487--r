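#' Select risk-score SNPs from the three association analyses
#'
#' The score uses the tag SNPs whose genotype effect on BMI is positive in
#' *all three* analyses — each cohort separately and the pooled sample. The
#' risk allele is the effect allele of those positive estimates. Applied to
#' the bundled summary statistics this yields six SNPs (two in FTO and one
#' each in MC4R, MTCH2, ETV5 and BDNF).
#'
#' @param assoc data.frame of association rows covering two cohorts and
#'   `"pooled"` (e.g. [run_panel()] output or [bmi_summary_stats()]).
#' @param tags optional character vector restricting candidates to tag SNPs.
#' @return data.frame with `snp_id` and `risk_allele`; zero rows (with a
#'   warning) if no SNP qualifies.
#' @export
select_grs_snps <- function(assoc, tags = NULL) {
  if (!is.null(tags)) assoc <- assoc[assoc$snp_id %in% tags, , drop = FALSE]
  analyses <- unique(assoc$cohort)
  if (!"pooled" %in% analyses || length(analyses) < 3L)
    stopf("need association rows for two cohorts and the pooled analysis")
  snps <- unique(assoc$snp_id)
  sel <- vapply(snps, function(s) {
    rows <- assoc[assoc$snp_id == s, ]
    nrow(rows) == length(analyses) && all(rows$beta > 0)
  }, TRUE)
  if (!any(sel)) {
    warnf("no SNP has a positive effect in all analyses; empty score")
    return(data.frame(snp_id = character(0), risk_allele = character(0)))
  }
  chosen <- assoc[assoc$cohort == "pooled" & assoc$snp_id %in% snps[sel], ]
  data.frame(snp_id = chosen$snp_id, risk_allele = chosen$effect_allele,
             stringsAsFactors = FALSE)
}

#' Risk-allele weights for the score
#'
#' Weights are the pooled-analysis per-allele effect sizes of the selected
#' SNPs (all positive after risk-allele orientation); `mean_weight` is their
#' arithmetic mean, used to re-scale the score.
#'
#' @param assoc association table containing `"pooled"` rows.
#' @param selection output of [select_grs_snps()].
#' @return data.frame of class `grs_weights` with `snp_id`, `risk_allele`,
#'   `weight` and a `mean_weight` attribute.
#' @export
grs_weights <- function(assoc, selection) {
  pooled <- assoc[assoc$cohort == "pooled", ]
  m <- match(selection$snp_id, pooled$snp_id)
  if (anyNA(m)) stopf("pooled results missing for: %s",
                      paste(selection$snp_id[is.na(m)], collapse = ", "))
  w <- pooled$beta[m]
  if (any(w <= 0)) stopf("weights must be positive after risk-allele orientation")
  out <- data.frame(snp_id = selection$snp_id,
                    risk_allele = selection$risk_allele,
                    weight = w, stringsAsFactors = FALSE)
  attr(out, "mean_weight") <- mean(w)
  class(out) <- c("grs_weights", class(out))
  out
}

#' Weighted genetic risk score per individual
#'
#' For each individual the 0/1/2 risk-allele counts are weighted by the SNP
#' effect sizes, re-scaled by dividing by the mean effect size, summed, and
#' rounded to the nearest integer (ties away from zero). A missing genotype
#' is replaced by twice the cohort risk-allele frequency (so that every
#' individual is scored) unless `missing = "drop"`, which leaves incomplete
#' individuals unscored (`NA`).
#'
#' @param genotypes a [geno_matrix()] containing the selected SNPs.
#' @param weights a [grs_weights()] table.
#' @param panel [snp_panel()]-style annotation (for allele orientation).
#' @param sex optional per-individual sex vector (X-linked orientation).
#' @param missing `"impute"` (default) or `"drop"`.
#' @param x_male_coding male X coding, `"0-1"` or `"0-2"`.
#' @return data.frame of class `grs_result`: `individual_id`, `cohort`,
#'   `raw_score`, `integer_score`.
#' @export
compute_wgrs <- function(genotypes, weights, panel, sex = NULL,
                         missing = c("impute", "drop"),
                         x_male_coding = "0-1") {
  missing <- match.arg(missing)
  mw <- attr(weights, "mean_weight") %||% mean(weights$weight)
  ids <- rownames(genotypes$counts)
  cohort <- genotypes$cohort[ids]
  dose <- sapply(seq_len(nrow(weights)), function(j) {
    orient_dosage(genotypes, weights$snp_id[j], weights$risk_allele[j],
                  panel, sex = sex, x_male_coding = x_male_coding)
  })
  dose <- matrix(dose, nrow = length(ids),
                 dimnames = list(ids, weights$snp_id))
  if (missing == "impute") {
    for (j in seq_len(ncol(dose))) {
      na <- is.na(dose[, j])
      if (!any(na)) next
      for (co in unique(cohort[na])) {
        in_co <- cohort == co
        raf <- mean(dose[in_co & !na, j]) / 2
        dose[na & in_co, j] <- 2 * raf
      }
    }
  }
  raw <- as.vector(dose %*% weights$weight) / mw
  out <- data.frame(individual_id = ids, cohort = unname(cohort),
                    raw_score = raw,
                    integer_score = round_half_away(raw),
                    stringsAsFactors = FALSE)
  class(out) <- c("grs_result", class(out))
  out
}

#' Age- and sex-adjusted BMI by score quintile
#'
#' Individuals are ranked by integer score and cut at the 20/40/60/80th
#' percentiles with ties assigned to the lower quintile (exact 20% groups are
#' impossible on an integer score). Adjusted quintile means and 95% CIs come
#' from regressing BMI on quintile indicators plus age and sex, evaluated at
#' the sample-mean covariates.
#'
#' @param score integer risk scores.
#' @param bmi outcome, kg/m2.
#' @param age,sex covariates (`sex` as `"male"`/`"female"` or 0/1).
#' @return list with `quintiles` (data.frame: quintile, n, mean_score,
#'   adj_mean, ci_lo, ci_hi) and `q5_minus_q1` (kg/m2).
#' @export
quintile_gradient <- function(score, bmi, age, sex) {
  if (is.character(sex) || is.factor(sex)) sex <- as.integer(sex == "female")
  cc <- stats::complete.cases(score, bmi, age, sex)
  score <- score[cc]; bmi <- bmi[cc]; age <- age[cc]; sex <- sex[cc]
  thr <- stats::quantile(score, c(.2, .4, .6, .8), type = 1)
  qn <- vapply(score, function(s) 1L + sum(s > thr), 1L)
  present <- sort(unique(qn))
  if (length(present) < 5L)
    warnf("only %d non-empty quintile groups after tie handling", length(present))
  qf <- factor(qn, levels = present)
  df <- data.frame(bmi = bmi, qf = qf)
  # constant covariates (e.g. a single-sex subset) drop out of the model
  if (stats::sd(age) > 0) df$age <- age
  if (stats::sd(sex) > 0) df$sex <- sex
  fit <- stats::lm(bmi ~ ., data = df)
  V <- stats::vcov(fit)
  co <- stats::coef(fit)
  tcrit <- stats::qt(0.975, fit$df.residual)
  rows <- lapply(seq_along(present), function(i) {
    cvec <- stats::setNames(numeric(length(co)), names(co))
    cvec["(Intercept)"] <- 1
    if (i > 1L) cvec[paste0("qf", present[i])] <- 1
    if ("age" %in% names(cvec)) cvec["age"] <- mean(age)
    if ("sex" %in% names(cvec)) cvec["sex"] <- mean(sex)
    est <- sum(cvec * co)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    data.frame(quintile = present[i], n = sum(qn == present[i]),
               mean_score = mean(score[qn == present[i]]),
               adj_mean = est, ci_lo = est - tcrit * se, ci_hi = est + tcrit * se)
  })
  qdf <- do.call(rbind, rows)
  list(quintiles = qdf,
       q5_minus_q1 = qdf$adj_mean[nrow(qdf)] - qdf$adj_mean[1])
}

#' Pearson correlation between score and BMI
#'
#' @param score integer risk scores (non-constant).
#' @param bmi outcome vector.
#' @return list with `r` and the two-sided t-based `p`.
#' @export
score_bmi_correlation <- function(score, bmi) {
  cc <- stats::complete.cases(score, bmi)
  score <- score[cc]; bmi <- bmi[cc]
  if (length(score) < 3L) stopf("need at least 3 individuals")
  if (stats::sd(score) == 0) stopf("undefined: score is constant")
  ct <- stats::cor.test(score, bmi, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' AUC of the score for obesity
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that a
#' random obese individual outscores a random non-obese one, counting ties
#' as one half: `(concordant + 0.5 * tied) / (n_case * n_control)`.
#'
#' @param score risk scores.
#' @param obesity logical case flags (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
auc_obesity <- function(score, obesity) {
  cc <- stats::complete.cases(score, obesity)
  score <- score[cc]; obesity <- as.logical(obesity[cc])
  n1 <- sum(obesity); n0 <- sum(!obesity)
  if (n1 == 0L || n0 == 0L) stopf("undefined: both classes must be present")
  r <- rank(score)
  (sum(r[obesity]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
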