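#' Run the full candidate-gene analysis pipeline
#'
#' Orchestrates the analysis stages in the study's order: sample/SNP QC,
#' per-cohort and pooled additive association, two-cohort meta-analysis with
#' heterogeneity statistics, and the weighted genetic risk score with
#' quintile-gradient, correlation and ROC/AUC evaluation. With the same
#' inputs, configuration and seed the report (and any files written) is
#' identical across runs.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes matching [phenotype_table()].
#' @param panel [snp_panel()]-style annotation.
#' @param config a [study_config()].
#' @param meta run the meta-analysis stage (requires two cohorts).
#' @param grs build and evaluate the weighted risk score.
#' @param include_dm2 adjust association models for the diabetes flag.
#' @param out_dir optional directory; when given, QC, association, meta and
#'   score tables are written there as tab-delimited files.
#' @return list of class `wgrs_report` with elements `qc`, `assoc`, `meta`,
#'   `grs` (selection, weights, scores, per-analysis evaluation),
#'   `bonferroni_threshold` and `config`.
#' @export
run_pipeline <- function(genotypes, phenotypes, panel, config = study_config(),
                         meta = TRUE, grs = TRUE, include_dm2 = FALSE,
                         out_dir = NULL) {
  if (!all(rownames(genotypes$counts) %in% phenotypes$individual_id))
    stopf("all genotyped individuals must appear in the phenotype table")
  cohorts <- unique(phenotypes$cohort[match(rownames(genotypes$counts),
                                            phenotypes$individual_id)])
  if (meta && length(cohorts) < 2L)
    stopf("configuration error: meta-analysis requested with %d cohort(s)",
          length(cohorts))
  qc <- apply_qc(genotypes, phenotypes, config, panel)
  assoc <- run_panel(qc$genotypes, phenotypes, panel, config, include_dm2)
  thr <- bonferroni_threshold(config$alpha, config$n_independent_tests)

  meta_res <- NULL
  if (meta) meta_res <- run_meta(assoc[assoc$cohort != "pooled", ], panel)

  grs_res <- NULL
  if (grs) {
    tags <- panel$snp_id[panel$is_tag %in% TRUE]
    selection <- select_grs_snps(assoc, tags = tags)
    if (nrow(selection) > 0L) {
      w <- grs_weights(assoc, selection)
      ids <- rownames(qc$genotypes$counts)
      ph <- phenotypes[match(ids, phenotypes$individual_id), ]
      scores <- compute_wgrs(subset_geno(qc$genotypes, snps = selection$snp_id),
                             w, panel, sex = ph$sex,
                             missing = config$grs_missing,
                             x_male_coding = config$x_male_coding)
      evals <- list()
      for (an in c(sort(cohorts), if (length(cohorts) > 1L) "pooled")) {
        sel <- if (an == "pooled") rep(TRUE, length(ids)) else ph$cohort == an
        sc <- scores$integer_score[sel]
        if (all(is.na(sc))) next
        evals[[an]] <- list(
          quintiles = quintile_gradient(sc, ph$bmi[sel], ph$age[sel], ph$sex[sel]),
          correlation = score_bmi_correlation(sc, ph$bmi[sel]),
          auc = auc_obesity(sc, ph$obesity[sel])
        )
      }
      grs_res <- list(selection = selection, weights = w, scores = scores,
                      evaluation = evals)
    } else {
      grs_res <- list(selection = selection, weights = NULL, scores = NULL,
                      evaluation = list())
    }
  }
  report <- structure(list(qc = qc, assoc = assoc, meta = meta_res,
                           grs = grs_res, bonferroni_threshold = thr,
                           config = config),
                      class = "wgrs_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write the report bundle as tab-delimited files
#'
#' @param report a `wgrs_report`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$qc$snps, "qc_snps.tsv")
  wt(report$qc$individuals, "qc_individuals.tsv")
  wt(report$assoc, "association.tsv")
  if (!is.null(report$meta)) wt(report$meta, "meta_analysis.tsv")
  if (!is.null(report$grs) && !is.null(report$grs$scores)) {
    wt(report$grs$scores, "grs_scores.tsv")
    qs <- do.call(rbind, lapply(names(report$grs$evaluation), function(an) {
      cbind(analysis = an, report$grs$evaluation[[an]]$quintiles$quintiles)
    }))
    wt(qs, "grs_quintiles.tsv")
  }
  writeLines(c(
    sprintf("bonferroni_threshold\t%s", format(signif(report$bonferroni_threshold, 3))),
    sprintf("n_individuals_excluded\t%d", report$qc$n_individuals_excluded),
    sprintf("n_snps_excluded\t%d", report$qc$n_snps_excluded)
  ), file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}

#' @export
print.wgrs_report <- function(x, ...) {
  cat("Candidate-gene BMI analysis report\n")
  cat(sprintf("  Bonferroni-corrected significance threshold: %s\n",
              format(signif(x$bonferroni_threshold, 3))))
  cat(sprintf("  QC: %d individual(s), %d SNP(s) excluded\n",
              x$qc$n_individuals_excluded, x$qc$n_snps_excluded))
  sig <- x$assoc[x$assoc$significant_bonferroni, ]
  cat(sprintf("  Bonferroni-significant associations: %d\n", nrow(sig)))
  if (nrow(sig)) print(sig[, c("snp_id", "cohort", "beta", "se", "p")],
                       row.names = FALSE)
  if (!is.null(x$meta))
    cat(sprintf("  Meta-analysis: %d SNP(s), %d excluded for allele problems\n",
                nrow(x$meta), sum(x$meta$excluded)))
  if (!is.null(x$grs) && nrow(x$grs$selection)) {
    cat(sprintf("  wGRS: %d SNPs (%s)\n", nrow(x$grs$selection),
                paste(x$grs$selection$snp_id, collapse = ", ")))
    for (an in names(x$grs$evaluation)) {
      ev <- x$grs$evaluation[[an]]
      cat(sprintf("    %s: Q5-Q1 = %.2f kg/m2, r = %.3f, AUC = %.3f\n",
                  an, ev$quintiles$q5_minus_q1, ev$correlation$r, ev$auc))
    }
  }
  invisible(x)
}
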