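test_that("EM haplotype frequencies equal allele/haplotype counts in trivial cases", {
  set.seed(51)
  g <- matrix(rbinom(60, 2, 0.35), ncol = 1, dimnames = list(NULL, "s1"))
  em <- em_haplotype_frequencies(g)
  f1 <- mean(g) / 2
  expect_equal(unname(em$freqs), c(1 - f1, f1), tolerance = 1e-8)

  # fully homozygous individuals: phase is unambiguous
  gh <- cbind(s1 = c(0, 0, 2, 2, 2, 0), s2 = c(0, 2, 2, 0, 2, 0))
  em2 <- em_haplotype_frequencies(gh)
  expect_equal(unname(em2$freqs),
               c(4, 2, 2, 4) / 12,  # direct haplotype counts over 2n copies
               tolerance = 1e-8)
  expect_true(em2$converged)
})

test_that("EM log-likelihood dominates a grid search over the 3-simplex", {
  set.seed(52)
  pool <- simulate_haplotype_pool(c(0.35, 0.4), 0.5)
  cfg_g <- matrix(NA_integer_, 30, 2, dimnames = list(NULL, c("a", "b")))
  h <- sample(nrow(pool$haplotypes), 60, TRUE, prob = pool$freqs)
  cfg_g[] <- pool$haplotypes[h[1:30], ] + pool$haplotypes[h[31:60], ]
  em <- em_haplotype_frequencies(cfg_g)
  g1 <- cfg_g[, 1]; g2 <- cfg_g[, 2]
  best_grid <- -Inf
  step <- 0.01
  for (f00 in seq(0, 1, step)) for (f01 in seq(0, 1 - f00, step)) {
    for (f10 in seq(0, 1 - f00 - f01, step)) {
      f <- c(f00, f01, f10, 1 - f00 - f01 - f10)
      if (any(f < 0)) next
      ll <- suppressWarnings(loglik_2snp(f, g1, g2))
      if (is.finite(ll) && ll > best_grid) best_grid <- ll
    }
  }
  expect_gte(em$loglik, best_grid - 1e-9)
})

test_that("EM dosages sum to two and implied allele freqs match genotypes", {
  set.seed(53)
  pool <- simulate_haplotype_pool(c(0.3, 0.3, 0.45), c(0.8, 0.5))
  n <- 150
  h1 <- sample(nrow(pool$haplotypes), n, TRUE, prob = pool$freqs)
  h2 <- sample(nrow(pool$haplotypes), n, TRUE, prob = pool$freqs)
  g <- pool$haplotypes[h1, ] + pool$haplotypes[h2, ]
  em <- em_haplotype_frequencies(g)
  expect_equal(unname(rowSums(em$dosage)), rep(2, n), tolerance = 1e-8)
  implied <- colSums(em$freqs * em$haplotypes)
  expect_equal(unname(implied), unname(colMeans(g) / 2), tolerance = 1e-6)
})

test_that("EM tolerates missing genotypes by expanding compatible diplotypes", {
  set.seed(54)
  pool <- simulate_haplotype_pool(c(0.4, 0.4), 0.9)
  n <- 200
  h1 <- sample(nrow(pool$haplotypes), n, TRUE, prob = pool$freqs)
  h2 <- sample(nrow(pool$haplotypes), n, TRUE, prob = pool$freqs)
  g <- pool$haplotypes[h1, ] + pool$haplotypes[h2, ]
  g[sample(n, 20), 1] <- NA
  em <- em_haplotype_frequencies(g)
  expect_true(em$converged)
  expect_equal(sum(em$freqs), 1, tolerance = 1e-10)
  expect_equal(unname(rowSums(em$dosage)), rep(2, n), tolerance = 1e-8)
  expect_error(em_haplotype_frequencies(matrix(0L, 4, 9)), "8-SNP")
})

test_that("r2 is 1 for self and perfect LD, matches the analytic value in pools", {
  set.seed(55)
  g <- rbinom(400, 2, 0.3)
  expect_equal(ld_r2(g, g), 1.0, tolerance = 1e-8)

  pool <- simulate_haplotype_pool(c(0.3, 0.3), 1)
  h1 <- sample(nrow(pool$haplotypes), 3000, TRUE, prob = pool$freqs)
  h2 <- sample(nrow(pool$haplotypes), 3000, TRUE, prob = pool$freqs)
  gm <- pool$haplotypes[h1, ] + pool$haplotypes[h2, ]
  expect_equal(ld_r2(gm[, 1], gm[, 2]), 1.0, tolerance = 1e-6)

  # known-D pool: estimated r2 approaches D^2/(pA pa pB pb) at large n
  pool2 <- simulate_haplotype_pool(c(0.35, 0.2), 0.45)
  h1 <- sample(nrow(pool2$haplotypes), 8000, TRUE, prob = pool2$freqs)
  h2 <- sample(nrow(pool2$haplotypes), 8000, TRUE, prob = pool2$freqs)
  gm2 <- pool2$haplotypes[h1, ] + pool2$haplotypes[h2, ]
  expect_equal(ld_r2(gm2[, 1], gm2[, 2]), 0.45, tolerance = 0.04)
  expect_error(ld_r2(rep(0, 50), rbinom(50, 2, 0.5)), "monomorphic")
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  set.seed(56)
  pool <- simulate_haplotype_pool(c(0.4, 0.3), 0.6)
  h1 <- sample(nrow(pool$haplotypes), 500, TRUE, prob = pool$freqs)
  h2 <- sample(nrow(pool$haplotypes), 500, TRUE, prob = pool$freqs)
  g <- pool$haplotypes[h1, ] + pool$haplotypes[h2, ]
  expect_equal(ld_r2(g[, 1], g[, 2]), ld_r2(g[, 2], g[, 1]), tolerance = 1e-8)
  expect_equal(ld_r2(2 - g[, 1], g[, 2]), ld_r2(g[, 1], g[, 2]), tolerance = 1e-8)
})

test_that("block and tag rules cover the analytic extremes", {
  ids <- paste0("s", 1:4)
  all1 <- matrix(1, 4, 4, dimnames = list(ids, ids))
  bt <- find_blocks_and_tags(all1, positions = 1:4)
  expect_equal(length(bt$blocks), 1)
  expect_equal(bt$blocks[[1]], ids)
  expect_equal(bt$tags, "s1")

  none <- diag(1, 4); dimnames(none) <- list(ids, ids)
  bt0 <- find_blocks_and_tags(none, positions = 1:4)
  expect_equal(length(bt0$blocks), 0)
  expect_setequal(bt0$tags, ids)
})

test_that("greedy tag count equals the exhaustive minimum on 8-SNP panels", {
  set.seed(57)
  for (rep in 1:5) {
    # planted structure: a 5-SNP high-LD block + 3 weakly related SNPs
    r2 <- diag(1, 8)
    r2[1:5, 1:5] <- runif(25, 0.9, 1); r2[1:5, 1:5][lower.tri(r2[1:5, 1:5])] <-
      t(r2[1:5, 1:5])[lower.tri(r2[1:5, 1:5])]
    diag(r2) <- 1
    r2[6:8, ] <- r2[, 6:8] <- runif(8 * 3, 0, 0.5)
    r2[lower.tri(r2)] <- t(r2)[lower.tri(r2)]
    diag(r2) <- 1
    dimnames(r2) <- list(paste0("s", 1:8), paste0("s", 1:8))
    bt <- find_blocks_and_tags(r2, positions = 1:8, r2_threshold = 0.9)
    expect_equal(length(bt$tags), oracle_min_tags(r2, 0.9))
  }
})

test_that("haplotype association recovers a planted noiseless effect", {
  set.seed(58)
  pool <- simulate_haplotype_pool(c(0.4, 0.35), 0.3)
  n <- 250
  h1 <- sample(nrow(pool$haplotypes), n, TRUE, prob = pool$freqs)
  h2 <- sample(nrow(pool$haplotypes), n, TRUE, prob = pool$freqs)
  g <- pool$haplotypes[h1, ] + pool$haplotypes[h2, ]
  em <- em_haplotype_frequencies(g)
  target <- "11"
  copies <- (apply(pool$haplotypes[h1, ], 1, paste, collapse = "") == target) +
    (apply(pool$haplotypes[h2, ], 1, paste, collapse = "") == target)
  bmi <- 25 + 1.5 * copies
  res <- haplotype_association(em, bmi)
  # with complete genotype data the 2-SNP diplotypes here are almost fully
  # phase-determined; the planted haplotype's beta is recovered closely
  expect_equal(res$beta[res$haplotype == target], 1.5, tolerance = 0.1)
  expect_true(all(res$freq >= 0.01))
})

test_that("haplotypes below the 1% floor are not tested", {
  set.seed(59)
  freqs <- c(0.995^2, 2 * 0.995 * 0.005, 0.005^2)
  g <- matrix(sample(0:2, 300, TRUE, prob = freqs), ncol = 1,
              dimnames = list(NULL, "s1"))
  em <- em_haplotype_frequencies(g)
  rare_freq <- mean(g) / 2
  res <- haplotype_association(em, rnorm(300, 27, 3))
  if (rare_freq < 0.01) expect_false("1" %in% res$haplotype)
  expect_true("0" %in% res$haplotype)
})

test_that("permuted BMI gives uniform haplotype p-values", {
  set.seed(60)
  pool <- simulate_haplotype_pool(c(0.4, 0.3), 0.5)
  n <- 120
  ps <- replicate(60, {
    h1 <- sample(nrow(pool$haplotypes), n, TRUE, prob = pool$freqs)
    h2 <- sample(nrow(pool$haplotypes), n, TRUE, prob = pool$freqs)
    g <- pool$haplotypes[h1, ] + pool$haplotypes[h2, ]
    em <- em_haplotype_frequencies(g)
    res <- haplotype_association(em, rnorm(n, 27, 4))
    res$p[1]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
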