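#' EM haplotype-frequency estimation from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a block of up to
#' `max_block_snps` biallelic SNPs, by expectation-maximization over the
#' latent diplotypes. The E-step assigns each individual a posterior over the
#' diplotypes compatible with their multilocus genotype (a missing call
#' expands the compatible set over that site rather than dropping the
#' individual); the M-step re-estimates haplotype frequencies from the
#' expected haplotype counts. Iteration starts from uniform frequencies and
#' stops when the L1 change drops below `tol` or after `max_iter` iterations;
#' the observed-data log-likelihood is checked to be non-decreasing at every
#' iteration.
#'
#' Individuals missing more than half of the block's sites are excluded from
#' estimation and receive `NA` dosages.
#'
#' @param geno matrix of 0/1/2 counts (individuals x SNPs), `NA` missing;
#'   counts refer to each SNP's counted allele (bit 1 of the haplotype code).
#' @param max_block_snps maximum block width (default 8).
#' @param tol L1 convergence tolerance on the frequency vector.
#' @param max_iter iteration cap; non-convergence sets a warning flag on the
#'   result rather than raising an error.
#' @return list of class `hap_block`: `snp_ids`, `haplotypes` (0/1 matrix over
#'   all retained haplotypes), `freqs`, `dosage` (individuals x haplotypes
#'   posterior-expected copy counts, rows summing to 2), `loglik`,
#'   `converged`, `n_iter`.
#' @export
em_haplotype_frequencies <- function(geno, max_block_snps = 8L,
                                     tol = 1e-8, max_iter = 1000L) {
  geno <- as.matrix(geno)
  k <- ncol(geno)
  if (k > max_block_snps)
    stopf("block of %d SNPs exceeds the %d-SNP limit", k, max_block_snps)
  snp_ids <- colnames(geno) %||% paste0("snp", seq_len(k))
  n_hap <- 2L^k
  hapbits <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  colnames(hapbits) <- snp_ids

  usable <- rowMeans(is.na(geno)) <= 0.5
  gu <- geno[usable, , drop = FALSE]

  # group individuals by genotype pattern; enumerate ordered compatible pairs
  pat_key <- apply(gu, 1L, function(g) paste(ifelse(is.na(g), "m", g), collapse = ""))
  pats <- unique(pat_key)
  pair_list <- lapply(pats, function(key) {
    g <- gu[match(key, pat_key), ]
    site_opts <- lapply(seq_len(k), function(j) {
      if (is.na(g[j])) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
      else if (g[j] == 0L) list(c(0L, 0L))
      else if (g[j] == 2L) list(c(1L, 1L))
      else list(c(0L, 1L), c(1L, 0L))
    })
    combos <- expand.grid(site_opts, KEEP.OUT.ATTRS = FALSE)
    h1 <- h2 <- integer(nrow(combos))
    for (j in seq_len(k)) {
      bits <- do.call(rbind, combos[[j]])
      h1 <- h1 + bits[, 1L] * 2L^(k - j)
      h2 <- h2 + bits[, 2L] * 2L^(k - j)
    }
    cbind(h1 = h1 + 1L, h2 = h2 + 1L)  # 1-based haplotype indices
  })
  names(pair_list) <- pats
  pat_n <- as.vector(table(factor(pat_key, levels = pats)))

  freqs <- rep(1 / n_hap, n_hap)
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    new_counts <- numeric(n_hap)
    ll <- 0
    for (i in seq_along(pats)) {
      pr <- pair_list[[i]]
      w <- freqs[pr[, 1L]] * freqs[pr[, 2L]]
      tot <- sum(w)
      ll <- ll + pat_n[i] * log(tot)
      w <- w / tot
      inc <- pat_n[i] * w
      for (r in seq_len(nrow(pr))) {
        new_counts[pr[r, 1L]] <- new_counts[pr[r, 1L]] + inc[r]
        new_counts[pr[r, 2L]] <- new_counts[pr[r, 2L]] + inc[r]
      }
    }
    if (ll < loglik - 1e-9)
      stopf("EM log-likelihood decreased (%.12g -> %.12g)", loglik, ll)
    loglik <- ll
    new_freqs <- new_counts / sum(new_counts)
    delta <- sum(abs(new_freqs - freqs))
    freqs <- new_freqs
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warnf("EM did not converge in %d iterations", max_iter)

  dosage <- matrix(NA_real_, nrow(geno), n_hap,
                   dimnames = list(rownames(geno),
                                   apply(hapbits, 1L, paste, collapse = "")))
  ui <- which(usable)
  for (i in seq_along(pats)) {
    pr <- pair_list[[i]]
    w <- freqs[pr[, 1L]] * freqs[pr[, 2L]]
    w <- w / sum(w)
    d <- numeric(n_hap)
    for (r in seq_len(nrow(pr))) {
      d[pr[r, 1L]] <- d[pr[r, 1L]] + w[r]
      d[pr[r, 2L]] <- d[pr[r, 2L]] + w[r]
    }
    rows <- ui[pat_key == pats[i]]
    dosage[rows, ] <- matrix(d, length(rows), n_hap, byrow = TRUE)
  }
  structure(list(snp_ids = snp_ids, haplotypes = hapbits, freqs = freqs,
                 dosage = dosage, loglik = loglik, converged = converged,
                 n_iter = iter),
            class = "hap_block")
}

#' Pairwise linkage disequilibrium r-squared
#'
#' r2 = D^2 / (pA(1-pA) pB(1-pB)), with D taken from the EM two-SNP haplotype
#' frequencies on shared complete cases (the standard composite approach for
#' unphased data).
#'
#' @param g1,g2 vectors of 0/1/2 counts.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  cc <- !is.na(g1) & !is.na(g2)
  g1 <- g1[cc]; g2 <- g2[cc]
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L)
    stopf("undefined: monomorphic SNP in r2 computation")
  em <- em_haplotype_frequencies(cbind(a = g1, b = g2))
  f <- em$freqs                             # order: 00, 01, 10, 11
  pa <- f[3] + f[4]
  pb <- f[2] + f[4]
  d <- f[4] - pa * pb
  min(1, d^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

#' LD matrix for a set of SNPs
#'
#' @param genotypes a [geno_matrix()] or plain counts matrix.
#' @param snp_ids optional subset/order (defaults to all, column order).
#' @return symmetric r-squared matrix of class `ld_matrix` with unit diagonal.
#' @export
ld_matrix <- function(genotypes, snp_ids = NULL) {
  counts <- if (inherits(genotypes, "geno_matrix")) genotypes$counts else genotypes
  if (!is.null(snp_ids)) counts <- counts[, snp_ids, drop = FALSE]
  k <- ncol(counts)
  r2 <- diag(1, k)
  dimnames(r2) <- list(colnames(counts), colnames(counts))
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    r2[i, j] <- r2[j, i] <- ld_r2(counts[, i], counts[, j])
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Blocks and tag SNPs from an LD matrix
#'
#' Blocks are maximal runs of consecutive (position-ordered) SNPs whose
#' pairwise r2 all reach `r2_threshold`. Tags are chosen greedily: repeatedly
#' pick the SNP that tags (r2 >= threshold, self included) the largest number
#' of still-untagged SNPs, breaking ties by lower position.
#'
#' @param ld symmetric r2 matrix (SNPs ordered by position).
#' @param positions numeric positions aligned with the matrix order (used for
#'   tie-breaking; defaults to matrix order).
#' @param r2_threshold block/tagging threshold (default 0.8).
#' @return list with `blocks` (list of snp-id vectors, singletons excluded)
#'   and `tags` (character vector).
#' @export
find_blocks_and_tags <- function(ld, positions = NULL, r2_threshold = 0.8) {
  k <- nrow(ld)
  ids <- rownames(ld) %||% paste0("snp", seq_len(k))
  positions <- positions %||% seq_len(k)
  blocks <- list()
  i <- 1L
  while (i <= k) {
    j <- i
    while (j < k && all(ld[i:(j + 1L), i:(j + 1L)] >= r2_threshold)) j <- j + 1L
    if (j > i) blocks[[length(blocks) + 1L]] <- ids[i:j]
    i <- j + 1L
  }
  covered <- rep(FALSE, k)
  tags <- character(0)
  while (!all(covered)) {
    gain <- vapply(seq_len(k), function(s) sum(ld[s, ] >= r2_threshold & !covered), 0)
    best <- which(gain == max(gain))
    best <- best[order(positions[best])][1L]
    tags <- c(tags, ids[best])
    covered <- covered | ld[best, ] >= r2_threshold
  }
  list(blocks = blocks, tags = tags)
}

#' Haplotype association with BMI via expected dosages
#'
#' One-vs-rest linear regression of BMI on the posterior-expected copy count
#' of each common haplotype (frequency >= `freq_floor`), adjusted for the
#' supplied covariates.
#'
#' @param block a `hap_block` from [em_haplotype_frequencies()].
#' @param bmi outcome vector aligned with the block's dosage rows.
#' @param covariates optional data.frame of covariates.
#' @param freq_floor minimum haplotype frequency to test (default 0.01).
#' @return data.frame with `haplotype` (0/1 string over the block's SNPs),
#'   `freq`, `beta`, `se`, `t_stat`, `p`; zero rows (with a warning) if no
#'   haplotype reaches the floor.
#' @export
haplotype_association <- function(block, bmi, covariates = NULL,
                                  freq_floor = 0.01) {
  keep <- which(block$freqs >= freq_floor)
  if (length(keep) == 0L) {
    warnf("no haplotype reaches the %g frequency floor", freq_floor)
    return(data.frame(haplotype = character(0), freq = numeric(0),
                      beta = numeric(0), se = numeric(0),
                      t_stat = numeric(0), p = numeric(0)))
  }
  out <- lapply(keep, function(h) {
    r <- additive_regression(bmi, block$dosage[, h], covariates)
    data.frame(haplotype = colnames(block$dosage)[h],
               freq = block$freqs[h],
               beta = r$beta, se = r$se, t_stat = r$t_stat, p = r$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
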