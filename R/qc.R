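#' Hardy-Weinberg exact test
#'
#' Exact conditional two-sided test of Hardy-Weinberg proportions for one
#' biallelic SNP. Conditioning on the observed allele counts, the p-value is
#' the sum of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed table — the standard
#' exact test used for genotype QC in genome-wide practice, preferable to the
#' asymptotic chi-square at low minor-allele counts.
#'
#' @param n_hom1 count of homozygotes for the first allele.
#' @param n_het count of heterozygotes.
#' @param n_hom2 count of homozygotes for the second allele.
#' @return the exact two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)  # the conditional mode: p = 1
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stopf("genotype counts must be >= 0")
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stopf("undefined: all genotype counts are zero")
  na <- 2L * n_hom1 + n_het       # copies of allele 1
  nb <- 2L * n_hom2 + n_het
  rare <- min(na, nb)
  if (rare == 0L) return(1)       # monomorphic: single possible table
  # possible heterozygote counts share the parity of the rare-allele total
  h <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- h * log(2) - lfactorial((na - h) / 2) - lfactorial(h) -
    lfactorial((nb - h) / 2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[h == n_het]
  if (length(obs) == 0L) stopf("heterozygote count inconsistent with allele totals")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Minor allele frequency of a genotype column
#'
#' @param counts vector of 0/1/2 allele counts with `NA` for missing.
#' @return `min(f, 1-f)` where `f` is the counted-allele fraction among
#'   non-missing genotypes.
#' @export
compute_maf <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0L) stopf("undefined: all genotypes missing")
  f <- sum(counts) / (2 * length(counts))
  min(f, 1 - f)
}

# counted-allele fraction handling hemizygous males on X
allele_freq_general <- function(counts, is_x = FALSE, male = NULL,
                                x_male_coding = "0-1") {
  keep <- !is.na(counts)
  if (!any(keep)) return(NA_real_)
  if (!is_x || is.null(male)) return(sum(counts[keep]) / (2 * sum(keep)))
  male <- male[keep]; counts <- counts[keep]
  if (x_male_coding == "0-2") counts[male] <- counts[male] / 2
  sum(counts[!male], counts[male]) / (2 * sum(!male) + sum(male))
}

#' Apply sample and SNP quality-control filters
#'
#' Implements the study's QC: individuals with a genotyping call rate below
#' `min_call_rate_individual` are removed first; then SNPs are removed if
#' monomorphic, if their call rate falls below `min_call_rate_snp`, if their
#' MAF falls below `min_maf`, or if the Hardy-Weinberg exact p-value (across
#' all remaining individuals) falls below `min_hwe_p`. HWE at X-linked SNPs is
#' computed in females only; a second HWE column is reported for the non-obese
#' ("control") subset but does not filter.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes matching [phenotype_table()] (sex and obesity flags).
#' @param config a [study_config()].
#' @param panel optional [snp_panel()] identifying X-linked SNPs.
#' @return list of class `qc_report`: `genotypes` (filtered), `snps` and
#'   `individuals` (per-record statistics, kept flags and exclusion reasons),
#'   `n_individuals_excluded`, `n_snps_excluded`.
#' @export
apply_qc <- function(genotypes, phenotypes, config = study_config(),
                     panel = NULL) {
  counts <- genotypes$counts
  ind_cr <- rowMeans(!is.na(counts))
  ind_kept <- ind_cr >= config$min_call_rate_individual
  individuals <- data.frame(
    individual_id = rownames(counts), cohort = unname(genotypes$cohort),
    call_rate = unname(ind_cr), kept = unname(ind_kept),
    exclusion_reason = ifelse(ind_kept, "", "call_rate"),
    stringsAsFactors = FALSE
  )
  counts <- counts[ind_kept, , drop = FALSE]

  ph <- phenotypes[match(rownames(counts), phenotypes$individual_id), ]
  male <- ph$sex == "male"
  nonobese <- !ph$obesity

  snp_ids <- colnames(counts)
  is_x <- rep(FALSE, length(snp_ids))
  if (!is.null(panel)) {
    m <- match(snp_ids, panel$snp_id)
    is_x <- !is.na(m) & panel$chromosome[m] == "X"
  }
  hwe_one <- function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }
  stats_row <- function(j, subset = TRUE) {
    g <- counts[subset, j]
    if (is_x[j]) hwe_one(g[!male[subset]]) else hwe_one(g)
  }
  call_rate <- colMeans(!is.na(counts))
  maf <- vapply(seq_along(snp_ids), function(j) {
    f <- allele_freq_general(counts[, j], is_x[j], male, config$x_male_coding)
    if (is.na(f)) NA_real_ else min(f, 1 - f)
  }, 0)
  hwe_p <- vapply(seq_along(snp_ids), function(j) stats_row(j), 0)
  hwe_p_controls <- vapply(seq_along(snp_ids), function(j)
    stats_row(j, subset = nonobese & !is.na(nonobese)), 0)

  reason <- character(length(snp_ids))
  reason[!is.na(maf) & maf == 0] <- "monomorphic"
  sel <- reason == "" & call_rate < config$min_call_rate_snp
  reason[sel] <- "call_rate"
  sel <- reason == "" & !is.na(maf) & maf < config$min_maf
  reason[sel] <- "maf"
  sel <- reason == "" & !is.na(hwe_p) & hwe_p < config$min_hwe_p
  reason[sel] <- "hwe"
  kept <- reason == ""

  snps <- data.frame(
    snp_id = snp_ids, call_rate = unname(call_rate), maf = unname(maf),
    hwe_p = unname(hwe_p), hwe_p_controls = unname(hwe_p_controls),
    kept = kept, exclusion_reason = reason, stringsAsFactors = FALSE
  )
  filtered <- geno_matrix(counts[, kept, drop = FALSE],
                          genotypes$count_allele[snp_ids[kept]],
                          genotypes$cohort[rownames(counts)])
  structure(list(
    genotypes = filtered, snps = snps, individuals = individuals,
    n_individuals_excluded = sum(!ind_kept), n_snps_excluded = sum(!kept)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: excluded %d individual(s), %d SNP(s); kept %d x %d\n",
              x$n_individuals_excluded, x$n_snps_excluded,
              nrow(x$genotypes$counts), ncol(x$genotypes$counts)))
  bad <- x$snps[!x$snps$kept, c("snp_id", "exclusion_reason")]
  if (nrow(bad)) print(bad, row.names = FALSE)
  invisible(x)
}
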