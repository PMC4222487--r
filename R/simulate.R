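#' Construct a haplotype pool with target allele frequencies and LD
#'
#' Builds a population haplotype pool over k SNPs whose allele frequencies
#' equal `target_freqs` and whose pairwise r-squared between adjacent SNPs
#' equals `target_r2`. For two SNPs the construction is exact and closed-form
#' (D chosen positive, coupling the counted alleles); for k > 2 the pool is a
#' first-order Markov chain over adjacent pairs, so the r of non-adjacent
#' pairs is approximately the product of the adjacent r's.
#'
#' For a pair with frequencies (pA, pB) the attainable positive-D bound is
#' `D_max = min(pA(1-pB), (1-pA)pB)`, giving a maximum r-squared of
#' `D_max^2 / (pA(1-pA) pB(1-pB))`; an infeasible target raises an error
#' naming that bound.
#'
#' @param target_freqs numeric vector of counted-allele frequencies in (0,1).
#' @param target_r2 scalar or vector (length k-1) of adjacent-pair r-squared
#'   targets in `[0,1]`.
#' @return list of class `hap_pool` with `haplotypes` (0/1 matrix, one row per
#'   haplotype; 1 = counted allele) and `freqs` (summing to 1).
#' @examples
#' simulate_haplotype_pool(c(0.3, 0.3), 1)  # two haplotypes: 11 (0.3), 00 (0.7)
#' @export
simulate_haplotype_pool <- function(target_freqs, target_r2) {
  k <- length(target_freqs)
  if (k < 2L) stopf("need at least two SNPs")
  if (any(target_freqs <= 0) || any(target_freqs >= 1))
    stopf("allele frequencies must be in (0,1)")
  r2 <- rep(target_r2, length.out = k - 1L)
  if (any(r2 < 0) || any(r2 > 1)) stopf("r2 targets must be in [0,1]")

  # per adjacent pair: joint haplotype distribution with positive D
  pair_joint <- function(p1, p2, r2pair) {
    p1 <- unname(p1); p2 <- unname(p2)
    dmax <- min(p1 * (1 - p2), (1 - p1) * p2)
    r2max <- dmax^2 / (p1 * (1 - p1) * p2 * (1 - p2))
    if (r2pair > r2max + 1e-12)
      stopf("feasibility error: target r2 %.4g exceeds bound %.4g for freqs (%g, %g)",
            r2pair, r2max, p1, p2)
    d <- sqrt(r2pair * p1 * (1 - p1) * p2 * (1 - p2))
    c(`11` = p1 * p2 + d, `10` = p1 * (1 - p2) - d,
      `01` = (1 - p1) * p2 - d, `00` = (1 - p1) * (1 - p2) + d)
  }
  joints <- lapply(seq_len(k - 1L), function(j)
    pair_joint(target_freqs[j], target_freqs[j + 1L], r2[j]))

  haps <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  colnames(haps) <- names(target_freqs) %||% paste0("snp", seq_len(k))
  dimnames(haps)[[1]] <- apply(haps, 1L, paste, collapse = "")
  freqs <- apply(haps, 1L, function(h) {
    p <- if (h[1] == 1) target_freqs[1] else 1 - target_freqs[1]
    for (j in seq_len(k - 1L)) {
      joint <- joints[[j]]
      pj <- if (h[j] == 1) target_freqs[j] else 1 - target_freqs[j]
      cond <- joint[paste0(h[j], h[j + 1L])] / pj
      p <- p * cond
    }
    unname(p)
  })
  keep <- freqs > 1e-12
  structure(list(haplotypes = haps[keep, , drop = FALSE],
                 freqs = freqs[keep] / sum(freqs[keep])),
            class = "hap_pool")
}

#' Pairwise r-squared implied by a haplotype pool
#'
#' @param pool a `hap_pool`.
#' @return symmetric matrix of r-squared values.
#' @export
pool_r2 <- function(pool) {
  k <- ncol(pool$haplotypes)
  p <- colSums(pool$haplotypes * pool$freqs)
  r2 <- diag(1, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    p11 <- sum(pool$freqs[pool$haplotypes[, i] == 1 & pool$haplotypes[, j] == 1])
    d <- p11 - p[i] * p[j]
    r2[i, j] <- r2[j, i] <- d^2 / (p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
  }
  dimnames(r2) <- list(colnames(pool$haplotypes), colnames(pool$haplotypes))
  r2
}

#' Generative configuration for one synthetic cohort
#'
#' Bundles the parameters of the data-generating model: per-SNP counted-allele
#' frequencies, optional LD blocks, additive per-allele BMI effects, the BMI
#' intercept and residual SD, age/sex distributions and their BMI effects,
#' missingness rates and the cohort label.
#'
#' With `cohort` naming one of the two reference cohorts, frequencies, effect
#' sizes and sample size default to that cohort's published calibration
#' ([bmi_summary_stats()], [cohort_reference()]); the intercept and residual
#' SD are then solved so the simulated BMI mean and SD match the cohort's
#' printed 28.6 +/- 5.2 (pizarra) or 26.4 +/- 4.2 (hortega). `cohort =
#' "pooled"` gives a single cohort at the pooled size with pooled effects.
#'
#' The BMI model is
#' `bmi = intercept + age_beta*age + sex_beta*[female] + sum_j beta_j g_ij + N(0, bmi_sd)`;
#' ages are normal truncated to 18-90 years and sex is Bernoulli. The defaults
#' `age_beta = 0.05` kg/m2 per year and `sex_beta = 0.6` kg/m2 (female-male)
#' are package choices of realistic magnitude; the calibration sources report
#' only marginal summaries.
#'
#' @param cohort `"pizarra"`, `"hortega"` or `"pooled"`.
#' @param n number of individuals.
#' @param maf named per-SNP counted-allele frequencies.
#' @param beta named per-SNP additive effects, kg/m2 per allele.
#' @param panel SNP annotation ([snp_panel()] subset) for the simulated SNPs.
#' @param ld_pool optional list of `hap_pool` objects; each pool's SNP names
#'   must match panel SNPs, and pooled SNPs are drawn as two haplotypes per
#'   individual instead of independent allele draws.
#' @param bmi_intercept,bmi_sd intercept and residual SD of the BMI model;
#'   `NULL` solves them from `bmi_target_mean`/`bmi_target_sd`.
#' @param bmi_target_mean,bmi_target_sd marginal BMI mean/SD to calibrate to.
#' @param age_mean,age_sd,female_fraction age/sex generation parameters.
#' @param age_beta,sex_beta covariate effects on BMI.
#' @param dm2_fraction Bernoulli rate of the type-2-diabetes flag.
#' @param miss_rate_snp scalar or named per-SNP missing-call rate.
#' @param miss_rate_ind per-individual missing-call rate (applied on top).
#' @param x_male_coding `"0-1"` or `"0-2"` storage of hemizygous males.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(cohort = "pizarra",
                              n = NULL, maf = NULL, beta = NULL,
                              panel = snp_panel(),
                              ld_pool = NULL,
                              bmi_intercept = NULL, bmi_sd = NULL,
                              bmi_target_mean = NULL, bmi_target_sd = NULL,
                              age_mean = NULL, age_sd = NULL,
                              female_fraction = NULL,
                              age_beta = 0.05, sex_beta = 0.6,
                              dm2_fraction = NULL,
                              miss_rate_snp = 0.01, miss_rate_ind = 0.005,
                              x_male_coding = "0-1") {
  ref <- cohort_reference()
  if (cohort %in% ref$cohort) {
    r <- ref[ref$cohort == cohort, ]
    stats_cohort <- cohort
  } else if (cohort == "pooled") {
    # pooled sample: size-weighted mixture of the two cohorts
    w <- ref$n / sum(ref$n)
    r <- data.frame(n = sum(ref$n),
                    age_mean = sum(w * ref$age_mean),
                    age_sd = sqrt(sum(w * ref$age_sd^2) +
                                    sum(w * (ref$age_mean - sum(w * ref$age_mean))^2)),
                    female_fraction = sum(w * ref$female_fraction),
                    bmi_mean = sum(w * ref$bmi_mean),
                    bmi_sd = sqrt(sum(w * ref$bmi_sd^2) +
                                    sum(w * (ref$bmi_mean - sum(w * ref$bmi_mean))^2)),
                    dm2_fraction = sum(w * ref$dm2_fraction))
    stats_cohort <- "pooled"
  } else {
    r <- data.frame(n = 1000L, age_mean = 50, age_sd = 15, female_fraction = 0.5,
                    bmi_mean = 27, bmi_sd = 4.5, dm2_fraction = 0.1)
    stats_cohort <- NULL
  }
  if (is.null(maf) || is.null(beta)) {
    if (is.null(stats_cohort))
      stopf("maf and beta must be given for an unnamed cohort")
    s <- bmi_summary_stats(stats_cohort)
    s <- s[s$snp_id %in% panel$snp_id, ]
    if (is.null(maf)) maf <- stats::setNames(s$eaf, s$snp_id)
    if (is.null(beta)) beta <- stats::setNames(s$beta, s$snp_id)
  }
  panel <- panel[panel$snp_id %in% names(maf), , drop = FALSE]
  beta <- beta[names(maf)]
  beta[is.na(beta)] <- 0
  names(beta) <- names(maf)

  n <- n %||% r$n
  age_mean <- age_mean %||% r$age_mean
  age_sd <- age_sd %||% r$age_sd
  female_fraction <- female_fraction %||% r$female_fraction
  dm2_fraction <- dm2_fraction %||% r$dm2_fraction
  bmi_target_mean <- bmi_target_mean %||% r$bmi_mean
  bmi_target_sd <- bmi_target_sd %||% r$bmi_sd

  if (any(maf <= 0 | maf >= 1)) stopf("allele frequencies must be in (0,1)")
  if (n < 1) stopf("n must be >= 1")

  m <- match(names(maf), panel$snp_id)
  is_x <- panel$chromosome[m] == "X"
  # expected dosage and variance per SNP (mixture over sex for X)
  male_mult <- if (x_male_coding == "0-1") 1 else 2
  eg <- ifelse(is_x,
               female_fraction * 2 * maf + (1 - female_fraction) * male_mult * maf,
               2 * maf)
  vg <- ifelse(is_x,
               female_fraction * (2 * maf * (1 - maf) + (2 * maf)^2) +
                 (1 - female_fraction) * (male_mult^2 * maf * (1 - maf) +
                                            (male_mult * maf)^2) - eg^2,
               2 * maf * (1 - maf))
  genetic_mean <- sum(beta * eg)
  genetic_var <- sum(beta^2 * vg)
  if (is.null(bmi_intercept))
    bmi_intercept <- bmi_target_mean - age_beta * age_mean -
      sex_beta * female_fraction - genetic_mean
  if (is.null(bmi_sd)) {
    resid_var <- bmi_target_sd^2 - age_beta^2 * age_sd^2 -
      sex_beta^2 * female_fraction * (1 - female_fraction) - genetic_var
    if (resid_var <= 0) stopf("covariate+genetic variance exceeds target BMI variance")
    bmi_sd <- sqrt(resid_var)
  }
  structure(list(
    cohort = if (cohort == "pooled") "pooled" else cohort,
    n = as.integer(n), maf = maf, beta = beta, panel = panel,
    ld_pool = ld_pool, bmi_intercept = bmi_intercept, bmi_sd = bmi_sd,
    age_mean = age_mean, age_sd = age_sd, female_fraction = female_fraction,
    age_beta = age_beta, sex_beta = sex_beta, dm2_fraction = dm2_fraction,
    miss_rate_snp = miss_rate_snp, miss_rate_ind = miss_rate_ind,
    x_male_coding = x_male_coding
  ), class = "cohort_sim_config")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate one synthetic cohort
#'
#' Draws genotypes per SNP as two independent allele draws (Hardy-Weinberg
#' proportions), or as two haplotype draws for SNPs covered by an LD pool;
#' hemizygous males at X-linked SNPs receive a single allele draw. BMI follows
#' the additive model of [cohort_sim_config()]; missingness is applied
#' completely at random after phenotype generation; the obesity flag is
#' derived from the (pre-missingness) BMI.
#'
#' @param config a [cohort_sim_config()].
#' @param seed optional integer seed.
#' @return list with `genotypes` (a [geno_matrix()]), `phenotypes` (a
#'   [phenotype_table()]) and `truth` (the config).
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  snp_ids <- names(config$maf)
  ids <- sprintf("%s_%05d", config$cohort, seq_len(n))
  age <- rnorm_trunc(n, config$age_mean, config$age_sd, 18, 90)
  female <- stats::rbinom(n, 1L, config$female_fraction)
  sex <- ifelse(female == 1L, "female", "male")

  m <- match(snp_ids, config$panel$snp_id)
  is_x <- config$panel$chromosome[m] == "X"
  counts <- matrix(NA_integer_, n, length(snp_ids), dimnames = list(ids, snp_ids))

  pooled_snps <- character(0)
  for (pool in config$ld_pool %||% list()) {
    psnps <- colnames(pool$haplotypes)
    h1 <- sample.int(length(pool$freqs), n, replace = TRUE, prob = pool$freqs)
    h2 <- sample.int(length(pool$freqs), n, replace = TRUE, prob = pool$freqs)
    counts[, psnps] <- pool$haplotypes[h1, , drop = FALSE] +
      pool$haplotypes[h2, , drop = FALSE]
    pooled_snps <- c(pooled_snps, psnps)
  }
  for (j in seq_along(snp_ids)) {
    if (snp_ids[j] %in% pooled_snps) next
    p <- config$maf[[j]]
    if (is_x[j]) {
      g <- integer(n)
      g[female == 1L] <- stats::rbinom(sum(female == 1L), 2L, p)
      gm <- stats::rbinom(sum(female == 0L), 1L, p)
      g[female == 0L] <- if (config$x_male_coding == "0-1") gm else 2L * gm
      counts[, j] <- g
    } else {
      counts[, j] <- stats::rbinom(n, 2L, p)
    }
  }

  bmi <- config$bmi_intercept + config$age_beta * age +
    config$sex_beta * female +
    as.vector(counts %*% config$beta) +
    stats::rnorm(n, 0, config$bmi_sd)
  dm2 <- stats::rbinom(n, 1L, config$dm2_fraction) == 1L

  # MCAR missingness, per-SNP then per-individual
  mr_snp <- rep(config$miss_rate_snp, length.out = length(snp_ids))
  if (!is.null(names(config$miss_rate_snp)))
    mr_snp <- config$miss_rate_snp[snp_ids]
  for (j in seq_along(snp_ids)) {
    if (mr_snp[j] > 0)
      counts[stats::runif(n) < mr_snp[j], j] <- NA_integer_
  }
  if (config$miss_rate_ind > 0) {
    drop <- matrix(stats::runif(n * length(snp_ids)) < config$miss_rate_ind,
                   n, length(snp_ids))
    counts[drop] <- NA_integer_
  }

  count_allele <- stats::setNames(config$panel$allele_a1[m], snp_ids)
  phen <- phenotype_table(data.frame(
    individual_id = ids, cohort = config$cohort, age = age, sex = sex,
    bmi = bmi, dm2 = dm2, stringsAsFactors = FALSE
  ))
  list(genotypes = geno_matrix(counts, count_allele,
                               stats::setNames(rep(config$cohort, n), ids)),
       phenotypes = phen,
       truth = config)
}

#' Generate the calibrated two-cohort study dataset
#'
#' Convenience wrapper producing both reference cohorts at their published
#' sizes and merging them into a single [geno_matrix()] and phenotype table.
#'
#' @param seed integer seed.
#' @param panel SNP panel (default [snp_panel()]).
#' @param ... passed through to [cohort_sim_config()] for both cohorts.
#' @return list with `genotypes`, `phenotypes`, `truth` (list of two configs).
#' @export
generate_two_cohort_study <- function(seed = 1L, panel = snp_panel(), ...) {
  set.seed(seed)
  piz <- generate_cohort(cohort_sim_config("pizarra", panel = panel, ...))
  hor <- generate_cohort(cohort_sim_config("hortega", panel = panel, ...))
  counts <- rbind(piz$genotypes$counts, hor$genotypes$counts)
  geno <- geno_matrix(counts, piz$genotypes$count_allele,
                      c(piz$genotypes$cohort, hor$genotypes$cohort))
  list(genotypes = geno,
       phenotypes = rbind(piz$phenotypes, hor$phenotypes),
       truth = list(pizarra = piz$truth, hortega = hor$truth))
}
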