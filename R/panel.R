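#' Candidate-gene SNP panel for the two-cohort BMI study
#'
#' The 26 tag SNPs in 23 obesity-candidate loci analysed in two Spanish
#' general-population cohorts (a rural southern cohort, "pizarra", and an
#' urban cohort, "hortega"). One SNP per row with gene symbol, chromosome,
#' 1-based position, the allele pair and a tag flag.
#'
#' `allele_a1` is the effect allele reported by the per-cohort association
#' analyses; `allele_a2` is its partner on the analysis strand. For two SNPs,
#' rs4712652 (PRL) and rs1424233 (MAF), the recorded pair is the genotyping
#' assay-strand pair, which is *incompatible* with the effect alleles the two
#' cohorts reported (A and G): these are synthetic reconstructions of a real
#' strand discrepancy (the true partner alleles were never published), and
#' they cause [align_alleles()] to exclude both SNPs from meta-analysis,
#' mirroring the original analysis.
#'
#' rs3813929 (HTR2C) is X-linked; all other SNPs are autosomal.
#'
#' @return data.frame with columns `snp_id`, `gene`, `chromosome`, `position`,
#'   `allele_a1`, `allele_a2`, `is_tag`.
#' @seealso [bmi_summary_stats()] for the matching per-cohort effect estimates.
#' @export
snp_panel <- function() {
  p <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
snp_id      gene    chromosome position   allele_a1 allele_a2
rs3101336   NEGR1   1          72523773   A G
rs10913469  SEC16B  1          176180142  C T
rs7566605   INSIG2  2          118552495  C G
rs4854344   TMEM18  2          628144     G T
rs17300539  ADIPOQ  3          188042154  A G
rs3774261   ADIPOQ  3          188054253  A G
rs7647305   ETV5    3          187316984  T C
rs10938397  GNPDA2  4          44877284   G A
rs12654778  ADRB2   5          148185934  A G
rs4712652   PRL     6          22186594   T C
rs10508503  PTER    10         16339957   T C
rs925946    BDNF    11         27623778   T G
rs10501087  BDNF    11         27626684   C A
rs10838738  MTCH2   11         47619625   G A
rs7138803   FAIM2   12         48533735   A G
rs6499640   FTO     16         52327178   G A
rs9939609   FTO     16         52378028   A T
rs7190492   FTO     16         52386253   A G
rs8044769   FTO     16         52396636   T C
rs8049439   ATXN2L  16         28745016   C T
rs1424233   MAF     16         78240252   T C
rs17782313  MC4R    18         56002077   C T
rs1805081   NPC1    18         19394430   G A
rs11084753  KCTD15  19         39013977   A G
rs6013029   CTNNBL1 20         35832994   T G
rs3813929   HTR2C   X          113724776  T C
")
  p$is_tag <- TRUE
  validate_snp_panel(p)
  p
}

#' Validate a SNP panel table
#'
#' Checks the invariants of the panel annotation: unique SNP ids, distinct
#' A/C/G/T alleles, positive positions.
#'
#' @param panel data.frame as returned by [snp_panel()].
#' @return the panel, invisibly, or an error.
#' @export
validate_snp_panel <- function(panel) {
  need <- c("snp_id", "gene", "chromosome", "position",
            "allele_a1", "allele_a2", "is_tag")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stopf("panel is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$snp_id)) stopf("duplicate snp_id in panel")
  bad <- !(panel$allele_a1 %in% VALID_ALLELES) | !(panel$allele_a2 %in% VALID_ALLELES)
  if (any(bad)) stopf("alleles must be one of A,C,G,T (offending: %s)",
                      paste(panel$snp_id[bad], collapse = ", "))
  if (any(panel$allele_a1 == panel$allele_a2)) stopf("allele_a1 must differ from allele_a2")
  if (any(panel$position <= 0)) stopf("positions must be > 0")
  invisible(panel)
}

#' Per-cohort SNP-BMI association summary statistics
#'
#' Effect estimates from additive-model linear regression of BMI (kg/m2) on
#' allele dosage, adjusted for age and sex, for the 26 tag SNPs in each of the
#' two cohorts and in the pooled sample. These printed summary statistics are
#' the calibration source for the synthetic-data generator (frequencies and
#' effect sizes), the worked-example inputs for the meta-analysis (the
#' per-cohort rows), and the inputs for the risk-score selection rule.
#'
#' `eaf` is the frequency of `effect_allele` in the analysed sample; `beta` is
#' kg/m2 per copy of the effect allele; `n` the complete-case count. Note the
#' differing effect alleles reported by the two cohorts for rs4712652 and
#' rs1424233 — irreconcilable with the panel's allele pair, hence the
#' meta-analysis drops both.
#'
#' @param analysis optional filter: one of `"pizarra"`, `"hortega"`, `"pooled"`.
#' @return data.frame with columns `snp_id`, `gene`, `cohort`, `effect_allele`,
#'   `eaf`, `n`, `beta`, `se`, `stat`, `p`.
#' @export
bmi_summary_stats <- function(analysis = NULL) {
  s <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
snp_id      gene   cohort  effect_allele eaf   n    beta     se   stat   p
rs9939609   FTO    pizarra A 0.398 848  0.875    0.23  3.79  0.0001573
rs9939609   FTO    hortega A 0.435 1345 0.1348   0.15  0.90  0.368
rs9939609   FTO    pooled  A 0.420 2215 0.2976   0.13  2.19  0.0287
rs8044769   FTO    pizarra T 0.463 848  -0.582   0.23  -2.54 0.0112
rs8044769   FTO    hortega T 0.455 1331 -0.1019  0.15  -0.68 0.495
rs8044769   FTO    pooled  T 0.458 2198 -0.257   0.13  -1.90 0.0571
rs7190492   FTO    pizarra A 0.328 845  -0.559   0.23  -2.34 0.0192
rs7190492   FTO    hortega A 0.337 1346 0.2065   0.16  1.29  0.195
rs7190492   FTO    pooled  A 0.333 2213 -0.07336 0.14  -0.51 0.6076
rs6499640   FTO    pizarra G 0.376 847  0.336    0.23  1.43  0.1511
rs6499640   FTO    hortega G 0.381 1347 0.09312  0.15  0.60  0.543
rs6499640   FTO    pooled  G 0.379 2216 0.2335   0.13  1.69  0.0911
rs17782313  MC4R   pizarra C 0.199 848  0.575    0.28  1.98  0.0478
rs17782313  MC4R   hortega C 0.191 1348 0.1167   0.19  0.60  0.544
rs17782313  MC4R   pooled  C 0.195 2218 0.3111   0.17  1.80  0.0716
rs10838738  MTCH2  pizarra G 0.352 845  0.453    0.24  1.88  0.0603
rs10838738  MTCH2  hortega G 0.353 1348 0.0972   0.15  0.62  0.536
rs10838738  MTCH2  pooled  G 0.353 2215 0.1698   0.14  1.19  0.2318
rs3101336   NEGR1  pizarra A 0.375 848  -0.084   0.24  -0.34 0.7277
rs3101336   NEGR1  hortega A 0.343 1348 -0.403   0.15  -2.64 0.0083
rs3101336   NEGR1  pooled  A 0.355 2210 -0.1586  0.14  -1.13 0.2561
rs8049439   ATXN2L pizarra C 0.375 848  -0.139   0.23  -0.58 0.5576
rs8049439   ATXN2L hortega C 0.338 1344 0.3292   0.15  2.13  0.0331
rs8049439   ATXN2L pooled  C 0.353 2209 0.1715   0.14  1.22  0.2198
rs3813929   HTR2C  pizarra T 0.157 847  -0.406   0.35  -1.16 0.2455
rs3813929   HTR2C  hortega T 0.182 1342 -0.4365  0.23  -1.89 0.0577
rs3813929   HTR2C  pooled  T 0.172 2211 -0.5551  0.20  -2.68 0.0073
rs12654778  ADRB2  pizarra A 0.388 848  0.271    0.23  1.16  0.2452
rs12654778  ADRB2  hortega A 0.380 1347 -0.1452  0.15  -0.95 0.339
rs12654778  ADRB2  pooled  A 0.382 2217 0.01463  0.13  0.10  0.9152
rs10913469  SEC16B pizarra C 0.142 848  0.392    0.32  1.21  0.2266
rs10913469  SEC16B hortega C 0.152 1347 -0.1609  0.20  -0.78 0.432
rs10913469  SEC16B pooled  C 0.148 2216 0.00939  0.18  0.05  0.96
rs4854344   TMEM18 pizarra G 0.172 847  -0.198   0.30  -0.64 0.5173
rs4854344   TMEM18 hortega G 0.169 1348 -0.3012  0.20  -1.48 0.138
rs4854344   TMEM18 pooled  G 0.170 2217 -0.243   0.18  -1.33 0.1815
rs7566605   INSIG2 pizarra C 0.327 846  0.101    0.24  0.41  0.676
rs7566605   INSIG2 hortega C 0.321 1348 -0.0301  0.16  -0.18 0.8514
rs7566605   INSIG2 pooled  C 0.322 2216 0.1152   0.14  0.79  0.4265
rs17300539  ADIPOQ pizarra A 0.126 844  -0.072   0.33  -0.21 0.8298
rs17300539  ADIPOQ hortega A 0.118 1348 0.1146   0.22  0.51  0.6082
rs17300539  ADIPOQ pooled  A 0.120 2214 0.0818   0.20  0.40  0.6838
rs3774261   ADIPOQ pizarra A 0.495 844  -0.036   0.22  -0.16 0.8727
rs3774261   ADIPOQ hortega A 0.461 1346 -0.0549  0.15  -0.36 0.7138
rs3774261   ADIPOQ pooled  A 0.473 2210 0.0609   0.13  0.45  0.6503
rs7647305   ETV5   pizarra T 0.205 838  0.022    0.28  0.079 0.9364
rs7647305   ETV5   hortega T 0.215 1325 0.2402   0.18  1.30  0.1927
rs7647305   ETV5   pooled  T 0.213 2175 0.2106   0.16  1.26  0.2077
rs10938397  GNPDA2 pizarra G 0.440 848  -0.338   0.22  -1.52 0.1278
rs10938397  GNPDA2 hortega G 0.455 1348 -0.048   0.15  -0.32 0.7492
rs10938397  GNPDA2 pooled  G 0.449 2218 -0.1687  0.13  -1.26 0.2078
rs4712652   PRL    pizarra A 0.453 828  0.203    0.23  0.87  0.3846
rs4712652   PRL    hortega G 0.487 1326 0.0367   0.15  0.24  0.8056
rs4712652   PRL    pooled  A 0.489 2175 -0.115   0.13  -0.84 0.3976
rs10508503  PTER   pizarra T 0.093 841  -0.119   0.39  -0.30 0.7617
rs10508503  PTER   hortega T 0.112 1315 -0.279   0.23  -1.21 0.2238
rs10508503  PTER   pooled  T 0.105 2174 -0.3695  0.21  -1.71 0.0866
rs925946    BDNF   pizarra T 0.282 848  0.128    0.24  0.51  0.6046
rs925946    BDNF   hortega T 0.266 1348 -0.071   0.16  -0.44 0.6578
rs925946    BDNF   pooled  T 0.272 2215 0.0795   0.14  0.54  0.5855
rs10501087  BDNF   pizarra C 0.253 845  0.033    0.26  0.12  0.8988
rs10501087  BDNF   hortega C 0.231 1348 0.0875   0.17  0.49  0.6231
rs10501087  BDNF   pooled  C 0.240 2214 0.1472   0.15  0.93  0.3493
rs7138803   FAIM2  pizarra A 0.352 844  0.155    0.24  0.65  0.5159
rs7138803   FAIM2  hortega A 0.352 1348 -0.0643  0.15  -0.42 0.675
rs7138803   FAIM2  pooled  A 0.351 2214 0.0513   0.14  0.36  0.7129
rs1424233   MAF    pizarra A 0.483 846  -0.192   0.23  -0.83 0.4074
rs1424233   MAF    hortega G 0.499 1348 0.2336   0.14  1.57  0.1158
rs1424233   MAF    pooled  A 0.495 2216 -0.2422  0.13  -1.79 0.0725
rs1805081   NPC1   pizarra G 0.329 845  -0.014   0.24  -0.05 0.9553
rs1805081   NPC1   hortega G 0.352 1345 0.0046   0.15  0.03  0.9758
rs1805081   NPC1   pooled  G 0.344 2212 -0.0463  0.14  -0.32 0.7432
rs11084753  KCTD15 pizarra A 0.395 846  0.093    0.23  0.39  0.6897
rs11084753  KCTD15 hortega A 0.352 1343 -0.1562  0.15  -1.01 0.31
rs11084753  KCTD15 pooled  A 0.367 2210 0.0573   0.13  0.41  0.6781
rs6013029   CTNNBL1 pizarra T 0.091 847 0.014    0.39  0.036 0.9708
rs6013029   CTNNBL1 hortega T 0.066 1348 -0.1522 0.30  -0.50 0.6133
rs6013029   CTNNBL1 pooled  T 0.076 2216 0.1139  0.25  0.44  0.6547
")
  if (!is.null(analysis)) {
    analysis <- match.arg(analysis, c("pizarra", "hortega", "pooled"))
    s <- s[s$cohort == analysis, , drop = FALSE]
    rownames(s) <- NULL
  }
  s
}

#' Printed characteristics of the two study cohorts
#'
#' Post-QC sample sizes and the age, sex and BMI summaries used to calibrate
#' the synthetic cohorts: the rural cohort is younger, more female and heavier
#' (36% obese) than the urban cohort (19% obese).
#'
#' @return data.frame, one row per cohort.
#' @export
cohort_reference <- function() {
  data.frame(
    cohort          = c("pizarra", "hortega"),
    n               = c(869L, 1425L),
    age_mean        = c(46.2, 54.4),
    age_sd          = c(13.8, 19.3),
    female_fraction = c(0.628, 0.496),
    bmi_mean        = c(28.6, 26.4),
    bmi_sd          = c(5.2, 4.2),
    obesity_fraction = c(0.360, 0.185),
    dm2_fraction    = c(0.189, 0.077),
    stringsAsFactors = FALSE
  )
}
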