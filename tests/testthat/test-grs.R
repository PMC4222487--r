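test_that("score SNP selection reproduces the published six-SNP set", {
  sel <- select_grs_snps(bmi_summary_stats())
  expect_setequal(sel$snp_id,
                  c("rs9939609", "rs6499640", "rs17782313",
                    "rs10838738", "rs7647305", "rs10501087"))
  expect_equal(nrow(sel), 6)
  # risk alleles are the printed effect alleles of the positive estimates
  expect_equal(sel$risk_allele[sel$snp_id == "rs9939609"], "A")
})

test_that("selection requires a positive beta in every analysis", {
  s <- bmi_summary_stats()
  s$beta <- -abs(s$beta)
  expect_warning(sel <- select_grs_snps(s), "no SNP")
  expect_equal(nrow(sel), 0)

  s2 <- bmi_summary_stats()
  s2$beta[s2$snp_id == "rs9939609" & s2$cohort == "hortega"] <- -0.01
  sel2 <- select_grs_snps(s2)
  expect_false("rs9939609" %in% sel2$snp_id)
  expect_equal(nrow(sel2), 5)
})

make_grs_fixture <- function(counts, risk = NULL, weights_beta) {
  snps <- colnames(counts)
  ids <- rownames(counts)
  geno <- geno_matrix(counts, setNames(rep("A", length(snps)), snps),
                      setNames(rep("c1", length(ids)), ids))
  panel <- data.frame(snp_id = snps, gene = "G", chromosome = "1",
                      position = seq_along(snps), allele_a1 = "A",
                      allele_a2 = "G", is_tag = TRUE, stringsAsFactors = FALSE)
  sel <- data.frame(snp_id = snps, risk_allele = "A", stringsAsFactors = FALSE)
  w <- data.frame(snp_id = snps, risk_allele = "A", weight = weights_beta)
  attr(w, "mean_weight") <- mean(weights_beta)
  class(w) <- c("grs_weights", class(w))
  list(geno = geno, panel = panel, weights = w)
}

test_that("wGRS weighting, rescaling and rounding follow the stated rule", {
  counts <- matrix(c(2, 1, 0,
                     0, 0, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("i1", "i2"), c("s1", "s2", "s3")))
  fx <- make_grs_fixture(counts, weights_beta = c(0.30, 0.12, 0.18))
  res <- compute_wgrs(fx$geno, fx$weights, fx$panel)
  expect_equal(res$raw_score[1], 0.72 / 0.20, tolerance = 1e-12)  # 3.6
  expect_equal(res$integer_score[1], 4)                           # ties away
  expect_equal(res$raw_score[2], 0)
  expect_equal(res$integer_score[2], 0)
})

test_that("equal weights make the score a plain risk-allele count", {
  set.seed(81)
  counts <- matrix(rbinom(60, 2, 0.4), 20, 3,
                   dimnames = list(sprintf("i%02d", 1:20), c("s1", "s2", "s3")))
  fx <- make_grs_fixture(counts, weights_beta = c(0.2, 0.2, 0.2))
  res <- compute_wgrs(fx$geno, fx$weights, fx$panel)
  expect_equal(res$raw_score, unname(rowSums(counts)), tolerance = 1e-12)
  expect_equal(res$integer_score, unname(rowSums(counts)))
})

test_that("scores are invariant to rescaling all weights", {
  set.seed(82)
  counts <- matrix(rbinom(90, 2, 0.3), 30, 3,
                   dimnames = list(sprintf("i%02d", 1:30), c("s1", "s2", "s3")))
  fx1 <- make_grs_fixture(counts, weights_beta = c(0.3, 0.12, 0.18))
  fx2 <- make_grs_fixture(counts, weights_beta = 7 * c(0.3, 0.12, 0.18))
  r1 <- compute_wgrs(fx1$geno, fx1$weights, fx1$panel)
  r2 <- compute_wgrs(fx2$geno, fx2$weights, fx2$panel)
  expect_equal(r1$raw_score, r2$raw_score, tolerance = 1e-12)
  expect_identical(r1$integer_score, r2$integer_score)
})

test_that("missing genotypes impute to twice the cohort risk-allele frequency", {
  counts <- matrix(c(2, 1, 0, 1, NA, 1), ncol = 2,
                   dimnames = list(c("i1", "i2", "i3"), c("s1", "s2")))
  fx <- make_grs_fixture(counts, weights_beta = c(0.2, 0.2))
  res <- compute_wgrs(fx$geno, fx$weights, fx$panel, missing = "impute")
  raf <- mean(c(1, 1)) / 2  # s2 non-missing dosages: i1=1, i3=1
  expect_equal(res$raw_score[2], 1 + 2 * raf, tolerance = 1e-12)
  res2 <- compute_wgrs(fx$geno, fx$weights, fx$panel, missing = "drop")
  expect_true(is.na(res2$raw_score[2]))
  expect_false(anyNA(res2$raw_score[c(1, 3)]))
})

test_that("quintile gradient is exact on a noiseless score-driven BMI", {
  set.seed(83)
  score <- sample(0:8, 600, TRUE)
  bmi <- 0.5 * score + 20
  qg <- quintile_gradient(score, bmi, age = rep(50, 600),
                          sex = rep("female", 600))
  for (i in seq_len(nrow(qg$quintiles))) {
    expect_equal(qg$quintiles$adj_mean[i],
                 20 + 0.5 * qg$quintiles$mean_score[i], tolerance = 1e-8)
  }
  expect_gt(qg$q5_minus_q1, 0)
  expect_equal(sum(qg$quintiles$n), 600)
})

test_that("quintile means shift by exactly an added BMI constant", {
  set.seed(84)
  score <- sample(0:8, 500, TRUE)
  age <- runif(500, 20, 70); sex <- rbinom(500, 1, 0.5)
  bmi <- 24 + 0.3 * score + 0.03 * age + 0.4 * sex + rnorm(500, 0, 3)
  q1 <- quintile_gradient(score, bmi, age, sex)
  q2 <- quintile_gradient(score, bmi + 5, age, sex)
  expect_equal(q2$quintiles$adj_mean, q1$quintiles$adj_mean + 5, tolerance = 1e-8)
  expect_equal(q2$q5_minus_q1, q1$q5_minus_q1, tolerance = 1e-8)
})

test_that("null score shows no quintile gradient on average", {
  set.seed(85)
  diffs <- replicate(60, {
    score <- sample(0:8, 400, TRUE)
    bmi <- rnorm(400, 27, 4)
    quintile_gradient(score, bmi, runif(400, 20, 70),
                      rbinom(400, 1, 0.5))$q5_minus_q1
  })
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 0.15)
})

test_that("score-BMI correlation matches the textbook formula", {
  score <- c(3, 5, 2, 8, 6, 4, 7, 1, 5, 4)
  bmi <- c(26.1, 28.4, 25.0, 31.2, 27.9, 26.8, 30.1, 24.2, 29.0, 26.5)
  r_hand <- sum((score - mean(score)) * (bmi - mean(bmi))) /
    sqrt(sum((score - mean(score))^2) * sum((bmi - mean(bmi))^2))
  sc <- score_bmi_correlation(score, bmi)
  expect_equal(sc$r, r_hand, tolerance = 1e-12)
  expect_equal(score_bmi_correlation(score, score)$r, 1, tolerance = 1e-12)
  expect_error(score_bmi_correlation(rep(3, 10), bmi), "constant")
})

test_that("AUC equals pair enumeration, ties counted half", {
  score <- c(1, 2, 2, 3, 4, 4, 5, 6)
  case <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(auc_obesity(score, case), oracle_auc(score, case),
               tolerance = 1e-12)
  set.seed(86)
  for (i in 1:20) {
    s <- sample(0:10, 30, TRUE)
    cs <- rbinom(30, 1, 0.4) == 1
    if (!any(cs) || all(cs)) next
    expect_equal(auc_obesity(s, cs), oracle_auc(s, cs), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  s <- sample(0:10, 200, TRUE); cs <- rbinom(200, 1, 0.3) == 1
  expect_equal(auc_obesity(s, cs),
               as.numeric(pROC::auc(pROC::roc(cs, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("AUC of a perfect separator is 1 and AUC(s)+AUC(-s)=1 without ties", {
  expect_equal(auc_obesity(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  expect_error(auc_obesity(1:5, rep(TRUE, 5)), "both classes")
  set.seed(87)
  s <- rnorm(50)  # continuous: tie-free
  cs <- rbinom(50, 1, 0.5) == 1
  expect_equal(auc_obesity(s, cs) + auc_obesity(-s, cs), 1, tolerance = 1e-12)
})
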