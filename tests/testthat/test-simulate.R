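test_that("haplotype pool constructions hit the analytic cases", {
  perfect <- simulate_haplotype_pool(c(0.3, 0.3), 1)
  key <- apply(perfect$haplotypes, 1, paste, collapse = "")
  expect_setequal(key, c("11", "00"))
  expect_equal(unname(perfect$freqs[key == "11"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(perfect$freqs[key == "00"]), 0.7, tolerance = 1e-12)

  indep <- simulate_haplotype_pool(c(0.2, 0.4), 0)
  expect_equal(nrow(indep$haplotypes), 4)
  key <- apply(indep$haplotypes, 1, paste, collapse = "")
  expect_equal(unname(indep$freqs[key == "11"]), 0.2 * 0.4, tolerance = 1e-12)
  expect_equal(unname(pool_r2(indep)[1, 2]), 0, tolerance = 1e-12)

  expect_error(simulate_haplotype_pool(c(0.1, 0.4), 0.9), "feasibility")
  expect_error(simulate_haplotype_pool(c(0.1, 0.4), 0.9), "0.1667")
})

test_that("pool allele frequencies and r2 match targets, also for chains", {
  freqs <- c(a = 0.3, b = 0.3, c = 0.4)
  pool <- simulate_haplotype_pool(freqs, c(0.9, 0.6))
  p <- colSums(pool$haplotypes * pool$freqs)
  expect_equal(unname(p), unname(freqs), tolerance = 1e-10)
  r2 <- pool_r2(pool)
  expect_equal(r2["a", "b"], 0.9, tolerance = 0.02)
  expect_equal(r2["b", "c"], 0.6, tolerance = 0.02)
  expect_equal(sum(pool$freqs), 1, tolerance = 1e-12)
})

test_that("realized allele frequencies track the configured values", {
  panel <- snp_panel()[1:5, ]
  maf <- setNames(c(0.17, 0.3, 0.45, 0.1, 0.25), panel$snp_id)
  cfg <- cohort_sim_config("pizarra", n = 5000, panel = panel, maf = maf,
                           beta = setNames(rep(0, 5), panel$snp_id),
                           miss_rate_snp = 0, miss_rate_ind = 0)
  sim <- generate_cohort(cfg, seed = 41)
  for (s in panel$snp_id) {
    f <- mean(sim$genotypes$counts[, s]) / 2
    tol <- 3 * sqrt(maf[[s]] * (1 - maf[[s]]) / (2 * 5000))
    expect_lt(abs(f - maf[[s]]), tol)
  }
})

test_that("null simulation yields uniform association p-values", {
  panel <- snp_panel()[2:7, ]
  cfg <- cohort_sim_config("pizarra", n = 5000, panel = panel,
                           beta = setNames(rep(0, 6), panel$snp_id),
                           miss_rate_snp = 0, miss_rate_ind = 0)
  sim <- generate_cohort(cfg, seed = 42)
  sexn <- as.integer(sim$phenotypes$sex == "female")
  ps <- vapply(panel$snp_id, function(s)
    additive_regression(sim$phenotypes$bmi, sim$genotypes$counts[, s],
                        data.frame(age = sim$phenotypes$age, sex = sexn))$p, 0)
  expect_true(all(ps > 1e-4))  # no spurious strong hit among 6 null SNPs
})

test_that("calibrated cohorts match the published BMI mean and SD", {
  sim <- generate_cohort(cohort_sim_config("pizarra"), seed = 43)
  expect_equal(nrow(sim$phenotypes), 869)
  expect_lt(abs(mean(sim$phenotypes$bmi) - 28.6), 0.5)
  expect_lt(abs(sd(sim$phenotypes$bmi) - 5.2), 0.5)
  sim2 <- generate_cohort(cohort_sim_config("hortega"), seed = 44)
  expect_equal(nrow(sim2$phenotypes), 1425)
  expect_lt(abs(mean(sim2$phenotypes$bmi) - 26.4), 0.5)
  expect_lt(abs(sd(sim2$phenotypes$bmi) - 4.2), 0.5)
  expect_true(all(sim$phenotypes$age >= 18 & sim$phenotypes$age <= 90))
  expect_equal(sim$phenotypes$obesity, sim$phenotypes$bmi >= 30)
})

test_that("simulated genotypes pass HWE and missingness matches config", {
  panel <- snp_panel()
  panel <- panel[panel$chromosome != "X", ][1:10, ]
  maf <- setNames(runif(10, 0.1, 0.5), panel$snp_id)
  cfg <- cohort_sim_config("pizarra", n = 2000, panel = panel, maf = maf,
                           beta = setNames(rep(0, 10), panel$snp_id),
                           miss_rate_snp = 0.03, miss_rate_ind = 0)
  set.seed(45)
  n_pass <- 0; n_tot <- 0; miss <- numeric(0)
  for (r in 1:10) {
    sim <- generate_cohort(cfg)
    for (s in panel$snp_id) {
      g <- sim$genotypes$counts[, s]
      miss <- c(miss, mean(is.na(g)))
      g <- g[!is.na(g)]
      p <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
      n_tot <- n_tot + 1
      n_pass <- n_pass + (p >= 0.001)
    }
  }
  expect_gte(n_pass / n_tot, 0.99)
  tol <- 3 * sqrt(0.03 * 0.97 / 2000)
  expect_lt(abs(mean(miss) - 0.03), tol)
})

test_that("X-linked males are hemizygous under both codings", {
  panel <- snp_panel()[snp_panel()$snp_id == "rs3813929", ]
  base <- list(n = 1000, panel = panel,
               maf = c(rs3813929 = 0.3), beta = c(rs3813929 = 0),
               miss_rate_snp = 0, miss_rate_ind = 0)
  cfg1 <- do.call(cohort_sim_config, c(list(cohort = "pizarra",
                                            x_male_coding = "0-1"), base))
  sim1 <- generate_cohort(cfg1, seed = 46)
  male <- sim1$phenotypes$sex == "male"
  expect_true(all(sim1$genotypes$counts[male, 1] %in% 0:1))
  cfg2 <- do.call(cohort_sim_config, c(list(cohort = "pizarra",
                                            x_male_coding = "0-2"), base))
  sim2 <- generate_cohort(cfg2, seed = 46)
  male2 <- sim2$phenotypes$sex == "male"
  expect_true(all(sim2$genotypes$counts[male2, 1] %in% c(0, 2)))
})

test_that("regression on simulated data recovers the generating effect", {
  panel <- snp_panel()[snp_panel()$snp_id == "rs9939609", ]
  cfg <- cohort_sim_config("pizarra", n = 848, panel = panel,
                           maf = c(rs9939609 = 0.398),
                           beta = c(rs9939609 = 0.875),
                           miss_rate_snp = 0, miss_rate_ind = 0)
  set.seed(47)
  covered <- 0; n_rep <- 60
  for (r in seq_len(n_rep)) {
    sim <- generate_cohort(cfg)
    res <- additive_regression(
      sim$phenotypes$bmi, sim$genotypes$counts[, 1],
      data.frame(age = sim$phenotypes$age,
                 sex = as.integer(sim$phenotypes$sex == "female")))
    ci <- res$beta + c(-1, 1) * qt(0.975, res$n - 4) * res$se
    covered <- covered + (ci[1] <= 0.875 && 0.875 <= ci[2])
  }
  expect_gte(covered / n_rep, 0.85)  # ~95% nominal; 60-replicate MC slack
})

test_that("LD-pool genotypes reproduce the target r2", {
  panel <- snp_panel()[snp_panel()$gene == "FTO", ][1:2, ]
  pool <- simulate_haplotype_pool(setNames(c(0.4, 0.42), panel$snp_id), 0.9)
  cfg <- cohort_sim_config("pizarra", n = 4000, panel = panel,
                           maf = setNames(c(0.4, 0.42), panel$snp_id),
                           beta = setNames(c(0, 0), panel$snp_id),
                           ld_pool = list(pool),
                           miss_rate_snp = 0, miss_rate_ind = 0)
  sim <- generate_cohort(cfg, seed = 48)
  r2 <- ld_r2(sim$genotypes$counts[, 1], sim$genotypes$counts[, 2])
  expect_equal(r2, 0.9, tolerance = 0.05)
})
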