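#' Genotype matrix container
#'
#' Stores unphased biallelic genotypes as counts (0, 1, 2 or `NA` for missing)
#' of a designated per-SNP count allele, for cohort-labelled individuals.
#'
#' @param counts integer matrix, individuals in rows (rownames = individual
#'   ids), SNPs in columns (colnames = snp ids); entries in `{0,1,2,NA}`.
#' @param count_allele named character vector, the allele whose copies are
#'   counted, one entry per SNP.
#' @param cohort named character vector of cohort labels, one per individual.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(counts, count_allele, cohort) {
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stopf("counts must have individual ids as rownames and snp ids as colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  count_allele <- count_allele[colnames(counts)]
  cohort <- cohort[rownames(counts)]
  x <- structure(
    list(counts = counts, count_allele = count_allele, cohort = cohort),
    class = "geno_matrix"
  )
  validate_geno_matrix(x)
  x
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs, cohorts: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (%d)", names(table(x$cohort)), table(x$cohort)),
                    collapse = ", ")))
  cat(sprintf("missing: %.2f%%\n", 100 * mean(is.na(x$counts))))
  invisible(x)
}

#' Validate a geno_matrix
#'
#' @param x a [geno_matrix()].
#' @param panel optional [snp_panel()]; if given, the count allele of every
#'   SNP must be one of the panel's two alleles.
#' @return `x` invisibly, or an error.
#' @export
validate_geno_matrix <- function(x, panel = NULL) {
  ok <- x$counts %in% c(0L, 1L, 2L) | is.na(x$counts)
  if (!all(ok)) stopf("genotype counts must be 0, 1, 2 or NA")
  if (length(x$count_allele) != ncol(x$counts) || anyNA(names(x$count_allele)))
    stopf("count_allele must be named, one entry per SNP")
  if (length(x$cohort) != nrow(x$counts))
    stopf("cohort must have one entry per individual")
  if (!all(x$count_allele %in% VALID_ALLELES))
    stopf("count alleles must be one of A,C,G,T")
  if (!is.null(panel)) {
    m <- match(colnames(x$counts), panel$snp_id)
    if (anyNA(m)) stopf("SNPs absent from panel: %s",
                        paste(colnames(x$counts)[is.na(m)], collapse = ", "))
    ok <- x$count_allele == panel$allele_a1[m] | x$count_allele == panel$allele_a2[m]
    if (!all(ok)) stopf("count allele not in panel allele pair for: %s",
                        paste(colnames(x$counts)[!ok], collapse = ", "))
  }
  invisible(x)
}

#' Subset a geno_matrix
#' @param x a `geno_matrix`.
#' @param individuals,snps optional character/logical/integer selectors.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(x, individuals = NULL, snps = NULL) {
  counts <- x$counts
  if (!is.null(individuals)) counts <- counts[individuals, , drop = FALSE]
  if (!is.null(snps)) counts <- counts[, snps, drop = FALSE]
  geno_matrix(counts, x$count_allele[colnames(counts)], x$cohort[rownames(counts)])
}

#' Orient genotype counts to a target allele
#'
#' Returns the dosage of `target_allele` for one SNP. If the stored count
#' allele is already the target the column is returned as-is; if it is the
#' partner allele the counts are reflected (`2 - g`, or `1 - g` for
#' hemizygous males at an X-linked SNP coded 0/1).
#'
#' @param geno a `geno_matrix`.
#' @param snp_id SNP to extract.
#' @param target_allele allele whose copies should be counted.
#' @param panel [snp_panel()] row(s) naming the allele pair and chromosome.
#' @param sex optional per-individual `"male"`/`"female"` vector (same order
#'   as individuals), needed to reflect X-linked male codes 0/1.
#' @param x_male_coding `"0-1"` or `"0-2"`; how hemizygous males are stored.
#' @return numeric vector of dosages with `NA` for missing.
#' @export
orient_dosage <- function(geno, snp_id, target_allele, panel,
                          sex = NULL, x_male_coding = "0-1") {
  g <- geno$counts[, snp_id]
  stored <- geno$count_allele[[snp_id]]
  row <- panel[panel$snp_id == snp_id, , drop = FALSE]
  if (nrow(row) == 0L) stopf("SNP %s not in panel", snp_id)
  pair <- c(row$allele_a1, row$allele_a2)
  if (!target_allele %in% pair)
    stopf("target allele %s not in allele pair {%s} of %s",
          target_allele, paste(pair, collapse = ","), snp_id)
  if (stored == target_allele) return(g)
  if (row$chromosome == "X" && identical(x_male_coding, "0-1") && !is.null(sex)) {
    male <- sex == "male"
    out <- ifelse(male, 1 - g, 2 - g)
    names(out) <- names(g)
    return(out)
  }
  2 - g
}

#' Assemble a phenotype table
#'
#' Validates the individual-level phenotype data and derives the obesity flag
#' (BMI >= 30 kg/m2).
#'
#' @param df data.frame with columns `individual_id`, `cohort`, `age` (years),
#'   `sex` (`"male"`/`"female"`), `bmi` (kg/m2) and optionally `dm2` (logical).
#' @return data.frame with an added logical `obesity` column.
#' @export
phenotype_table <- function(df) {
  need <- c("individual_id", "cohort", "age", "sex", "bmi")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("phenotypes missing columns: %s", paste(miss, collapse = ", "))
  if (!all(df$sex %in% c("male", "female"))) stopf("sex must be 'male' or 'female'")
  if (any(df$bmi <= 0, na.rm = TRUE)) stopf("bmi must be positive")
  if (is.null(df$dm2)) df$dm2 <- NA
  df$obesity <- df$bmi >= 30
  df
}

#' Study-wide analysis configuration
#'
#' Collects the QC thresholds, the multiple-testing correction, and the coding
#' conventions used across the pipeline. Defaults are the study's: 95% call
#' rate for individuals and SNPs, MAF >= 1%, Hardy-Weinberg exact p >= 0.001,
#' and a Bonferroni correction for 26 independent tests at alpha = 0.05
#' (threshold 0.05/26 = 0.00192).
#'
#' @param min_call_rate_snp,min_call_rate_individual call-rate floors in (0,1].
#' @param min_maf minor-allele-frequency floor in (0,1].
#' @param min_hwe_p Hardy-Weinberg exact-test p-value floor.
#' @param alpha family-wise significance level.
#' @param n_independent_tests Bonferroni divisor (>= 1).
#' @param grs_rounding `"half_away"`: integer risk scores round ties away from
#'   zero.
#' @param grs_missing `"impute"` replaces a missing genotype in the score by
#'   twice the cohort risk-allele frequency; `"drop"` scores complete cases only.
#' @param x_male_coding `"0-1"` (default) or `"0-2"` for hemizygous males.
#' @param pooled_cohort_covariate logical; include a cohort indicator in the
#'   pooled regression (default `TRUE`).
#' @param seed integer seed recorded with the run.
#' @return a list of class `study_config`.
#' @export
study_config <- function(min_call_rate_snp = 0.95,
                         min_call_rate_individual = 0.95,
                         min_maf = 0.01,
                         min_hwe_p = 0.001,
                         alpha = 0.05,
                         n_independent_tests = 26L,
                         grs_rounding = "half_away",
                         grs_missing = c("impute", "drop"),
                         x_male_coding = c("0-1", "0-2"),
                         pooled_cohort_covariate = TRUE,
                         seed = 1L) {
  fracs <- c(min_call_rate_snp, min_call_rate_individual, min_maf, min_hwe_p, alpha)
  if (any(fracs <= 0) || any(fracs > 1)) stopf("all fractions must be in (0,1]")
  if (n_independent_tests < 1) stopf("n_independent_tests must be >= 1")
  structure(list(
    min_call_rate_snp = min_call_rate_snp,
    min_call_rate_individual = min_call_rate_individual,
    min_maf = min_maf,
    min_hwe_p = min_hwe_p,
    alpha = alpha,
    n_independent_tests = as.integer(n_independent_tests),
    grs_rounding = grs_rounding,
    grs_missing = match.arg(grs_missing),
    x_male_coding = match.arg(x_male_coding),
    pooled_cohort_covariate = isTRUE(pooled_cohort_covariate),
    seed = as.integer(seed)
  ), class = "study_config")
}
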