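# Independent brute-force oracles used to validate the package's primitives.
# These deliberately use naive arithmetic (plain factorial(), direct normal
# equations, pair enumeration, grid search) so they share no code path with
# the implementation under test.

# Exact HWE p-value by direct enumeration with plain factorials.
# Valid while allele totals stay below factorial overflow (~170).
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het
  nb <- 2 * n_hom2 + n_het
  hs <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  prob <- sapply(hs, function(h) {
    naa <- (na - h) / 2; nbb <- (nb - h) / 2
    factorial(n) / (factorial(naa) * factorial(h) * factorial(nbb)) *
      2^h * factorial(na) * factorial(nb) / factorial(2 * n)
  })
  obs <- prob[hs == n_het]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# OLS via explicit normal equations.
oracle_ols <- function(y, X) {
  X <- cbind(1, X)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bh
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  V <- s2 * solve(t(X) %*% X)
  se <- unname(sqrt(diag(V)))
  t <- drop(bh) / se
  list(beta = unname(drop(bh)), se = se, t = unname(t),
       p = unname(2 * pt(-abs(t), df)))
}

# DerSimonian-Laird by direct formula evaluation.
oracle_dl <- function(b, s) {
  w <- 1 / s^2
  bf <- sum(w * b) / sum(w)
  q <- sum(w * (b - bf)^2)
  tau2 <- max(0, (q - (length(b) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (s^2 + tau2)
  list(tau2 = tau2, beta = sum(ws * b) / sum(ws), se = sum(ws)^-0.5,
       beta_fe = bf, se_fe = sum(w)^-0.5, q = q)
}

# AUC by enumeration over all case-control pairs.
oracle_auc <- function(score, case) {
  cs <- score[case]; ct <- score[!case]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Multilocus genotype log-likelihood given 4 haplotype freqs (2 SNPs),
# haplotype order 00, 01, 10, 11.
loglik_2snp <- function(f, g1, g2) {
  hap <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  ll <- 0
  for (i in seq_along(g1)) {
    p <- 0
    for (h1 in 1:4) for (h2 in 1:4) {
      if (hap[h1, 1] + hap[h2, 1] == g1[i] && hap[h1, 2] + hap[h2, 2] == g2[i])
        p <- p + f[h1] * f[h2]
    }
    ll <- ll + log(p)
  }
  ll
}

# Minimum number of tags covering all SNPs at r2 >= thr (exact set cover).
oracle_min_tags <- function(r2, thr) {
  k <- nrow(r2)
  for (size in 1:k) {
    for (comb in utils::combn(k, size, simplify = FALSE)) {
      covered <- apply(r2[comb, , drop = FALSE] >= thr, 2, any)
      if (all(covered)) return(size)
    }
  }
  k
}

# Small fixture with planted QC violations, built in code. Twenty clean
# filler SNPs keep individual call rates above 95% (one missing cell out of
# 24 SNPs is a 95.8% individual call rate), so the planted low-call SNP is
# caught by the SNP filter, not masked by the individual filter.
make_qc_fixture <- function(seed = 11) {
  set.seed(seed)
  n <- 120
  ids <- sprintf("i%03d", seq_len(n))
  fillers <- sapply(1:18, function(j) rbinom(n, 2, runif(1, 0.2, 0.5)))
  colnames(fillers) <- sprintf("filler%02d", 1:18)
  good1 <- rbinom(n, 2, 0.3)
  good2 <- rbinom(n, 2, 0.4)
  mono <- rep(0L, n)                       # monomorphic
  lowcall <- rbinom(n, 2, 0.3)
  lowcall[seq_len(round(0.1 * n))] <- NA   # 90% call rate
  hwe_bad <- rep(1L, n)                    # all heterozygous: extreme HWE violation
  rare <- c(rep(0L, n - 1), 1L)            # MAF below 1%
  counts <- cbind(good1 = good1, good2 = good2, mono = mono,
                  lowcall = lowcall, hwe_bad = hwe_bad, rare = rare, fillers)
  rownames(counts) <- ids
  ca <- setNames(rep("A", ncol(counts)), colnames(counts))
  geno <- geno_matrix(counts, ca, setNames(rep("c1", n), ids))
  phen <- phenotype_table(data.frame(
    individual_id = ids, cohort = "c1",
    age = runif(n, 20, 70), sex = sample(c("male", "female"), n, TRUE),
    bmi = rnorm(n, 27, 4), dm2 = FALSE, stringsAsFactors = FALSE))
  panel <- data.frame(snp_id = colnames(counts), gene = "G",
                      chromosome = "1", position = seq_len(ncol(counts)) * 1000L,
                      allele_a1 = "A", allele_a2 = "G", is_tag = TRUE,
                      stringsAsFactors = FALSE)
  list(geno = geno, phen = phen, panel = panel)
}

# Small clean two-cohort study for pipeline-level tests.
make_small_study <- function(seed = 5, n_piz = 180, n_hor = 220) {
  panel <- snp_panel()
  set.seed(seed)
  piz <- generate_cohort(cohort_sim_config("pizarra", n = n_piz, panel = panel,
                                           miss_rate_snp = 0.005,
                                           miss_rate_ind = 0))
  hor <- generate_cohort(cohort_sim_config("hortega", n = n_hor, panel = panel,
                                           miss_rate_snp = 0.005,
                                           miss_rate_ind = 0))
  geno <- geno_matrix(rbind(piz$genotypes$counts, hor$genotypes$counts),
                      piz$genotypes$count_allele,
                      c(piz$genotypes$cohort, hor$genotypes$cohort))
  list(genotypes = geno, phenotypes = rbind(piz$phenotypes, hor$phenotypes),
       panel = panel)
}
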