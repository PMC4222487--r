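#' Harmonize effect alleles of two cohort results
#'
#' Both cohorts must report an effect allele belonging to the panel's allele
#' pair. If the alleles agree the pair is returned unchanged; if they are
#' swapped within the pair, the second result is flipped (`beta` negated,
#' `eaf` complemented, allele relabelled) — unless the pair is
#' strand-ambiguous (A/T or C/G), in which case a swap cannot be told apart
#' from a strand difference and the SNP is excluded with reason
#' `"ambiguous_strand"`. An effect allele outside the panel pair excludes the
#' SNP with reason `"allele_mismatch"`.
#'
#' @param result_1,result_2 one-row association results (see
#'   [additive_regression()]) for the same SNP in two cohorts.
#' @param panel_row the matching [snp_panel()] row.
#' @return list with `result_1`, `result_2`, `excluded` (logical),
#'   `exclusion_reason` (`""` when kept).
#' @export
align_alleles <- function(result_1, result_2, panel_row) {
  if (!identical(result_1$snp_id, result_2$snp_id))
    stopf("results are for different SNPs")
  pair <- c(panel_row$allele_a1, panel_row$allele_a2)
  a1 <- result_1$effect_allele; a2 <- result_2$effect_allele
  if (!(a1 %in% pair) || !(a2 %in% pair)) {
    return(list(result_1 = result_1, result_2 = result_2,
                excluded = TRUE, exclusion_reason = "allele_mismatch"))
  }
  if (a1 == a2) {
    return(list(result_1 = result_1, result_2 = result_2,
                excluded = FALSE, exclusion_reason = ""))
  }
  if (is_ambiguous_pair(pair[1], pair[2])) {
    return(list(result_1 = result_1, result_2 = result_2,
                excluded = TRUE, exclusion_reason = "ambiguous_strand"))
  }
  result_2$beta <- -result_2$beta
  if (!is.null(result_2$t_stat)) result_2$t_stat <- -result_2$t_stat
  if (!is.null(result_2$eaf)) result_2$eaf <- 1 - result_2$eaf
  result_2$effect_allele <- a1
  list(result_1 = result_1, result_2 = result_2,
       excluded = FALSE, exclusion_reason = "")
}

#' Inverse-variance fixed-effect pooling
#'
#' Weights `w_i = 1/se_i^2`; pooled `beta = sum(w b)/sum(w)`,
#' `se = sum(w)^(-1/2)`, two-sided normal p-value.
#'
#' @param betas,ses study effect estimates and standard errors (>= 2 studies).
#' @return list with `beta`, `se`, `z`, `p`.
#' @export
fixed_effect_meta <- function(betas, ses) {
  if (length(betas) < 2L || length(betas) != length(ses))
    stopf("need >= 2 studies with matching SEs")
  if (any(ses <= 0)) stopf("standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sum(w)^(-0.5)
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cochran's Q and the I-squared heterogeneity index
#'
#' `Q = sum(w_i (b_i - beta_FE)^2)` on fixed-effect weights, compared to a
#' chi-square with `k - 1` df; `I2 = max(0, (Q - df)/Q) * 100` percent.
#'
#' @inheritParams fixed_effect_meta
#' @return list with `q`, `df`, `p_q`, `i2`.
#' @export
cochran_q_i2 <- function(betas, ses) {
  fe <- fixed_effect_meta(betas, ses)
  w <- 1 / ses^2
  q <- sum(w * (betas - fe$beta)^2)
  df <- length(betas) - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(q = q, df = df, p_q = stats::pchisq(q, df, lower.tail = FALSE), i2 = i2)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance,
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`, followed by
#' inverse-variance pooling on weights `1/(se_i^2 + tau2)`. When `Q <= df`
#' the estimate collapses to the fixed-effect result exactly.
#'
#' @inheritParams fixed_effect_meta
#' @return list with `tau2`, `beta`, `se`, `z`, `p`.
#' @export
dersimonian_laird <- function(betas, ses) {
  het <- cochran_q_i2(betas, ses)
  w <- 1 / ses^2
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (het$q - het$df) / denom)
  ws <- 1 / (ses^2 + tau2)
  beta <- sum(ws * betas) / sum(ws)
  se <- sum(ws)^(-0.5)
  z <- beta / se
  list(tau2 = tau2, beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-cohort meta-analysis over an association table
#'
#' For every SNP with results in both cohorts: harmonize effect alleles
#' ([align_alleles()]), then pool with the inverse-variance fixed-effect and
#' DerSimonian-Laird random-effects models and report Cochran's Q and I2.
#' SNPs failing harmonization are reported with `excluded = TRUE` and no
#' pooled estimates.
#'
#' @param assoc data.frame of per-cohort association rows (two cohort labels;
#'   any `"pooled"` rows are ignored).
#' @param panel [snp_panel()]-style annotation.
#' @return data.frame of class `meta_result` mirroring the heterogeneity
#'   table layout: `snp_id`, `effect_allele`, `p_fe`, `p_re`, `beta_fe`,
#'   `beta_re`, `se_fe`, `se_re`, `tau2`, `q`, `df`, `p_q`, `i2`, `excluded`,
#'   `exclusion_reason`.
#' @export
run_meta <- function(assoc, panel) {
  cohorts <- setdiff(unique(assoc$cohort), "pooled")
  if (length(cohorts) != 2L)
    stopf("configuration error: meta-analysis needs exactly 2 cohorts, found %d",
          length(cohorts))
  out <- lapply(unique(assoc$snp_id), function(snp) {
    r1 <- assoc[assoc$snp_id == snp & assoc$cohort == cohorts[1], ]
    r2 <- assoc[assoc$snp_id == snp & assoc$cohort == cohorts[2], ]
    if (nrow(r1) != 1L || nrow(r2) != 1L) return(NULL)
    pr <- panel[panel$snp_id == snp, , drop = FALSE]
    al <- align_alleles(r1, r2, pr)
    base <- data.frame(snp_id = snp, effect_allele = al$result_1$effect_allele,
                       stringsAsFactors = FALSE)
    if (al$excluded) {
      return(cbind(base, p_fe = NA_real_, p_re = NA_real_, beta_fe = NA_real_,
                   beta_re = NA_real_, se_fe = NA_real_, se_re = NA_real_,
                   tau2 = NA_real_, q = NA_real_, df = NA_integer_,
                   p_q = NA_real_, i2 = NA_real_, excluded = TRUE,
                   exclusion_reason = al$exclusion_reason))
    }
    b <- c(al$result_1$beta, al$result_2$beta)
    s <- c(al$result_1$se, al$result_2$se)
    fe <- fixed_effect_meta(b, s)
    het <- cochran_q_i2(b, s)
    re <- dersimonian_laird(b, s)
    cbind(base, p_fe = fe$p, p_re = re$p, beta_fe = fe$beta, beta_re = re$beta,
          se_fe = fe$se, se_re = re$se, tau2 = re$tau2, q = het$q,
          df = het$df, p_q = het$p_q, i2 = het$i2, excluded = FALSE,
          exclusion_reason = "")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("meta_result", class(res))
  res
}
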