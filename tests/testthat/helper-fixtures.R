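# fixtures and independent oracles shared across test files

# two perfectly separated diploid groups: group 1 fixed for allele 1,
# group 2 fixed for allele 2 at every locus
make_separable <- function(n_per = 5L, n_loci = 10L) {
  a1 <- rbind(matrix(2L, n_per, n_loci), matrix(0L, n_per, n_loci))
  tab <- matrix(0L, 2L * n_per, 2L * n_loci)
  tab[, seq(1L, 2L * n_loci, 2L)] <- a1
  tab[, seq(2L, 2L * n_loci, 2L)] <- 2L - a1
  genotype_matrix(tab, rep(seq_len(n_loci), each = 2L),
                  allow_monomorphic = TRUE)
}

# random diploid biallelic genotypes with no population structure
make_random_genotypes <- function(n = 6L, n_loci = 4L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a1 <- matrix(rbinom(n * n_loci, 2L, runif(n_loci, 0.2, 0.8)[
    rep(seq_len(n_loci), each = n)]), n, n_loci)
  tab <- matrix(0L, n, 2L * n_loci)
  tab[, seq(1L, 2L * n_loci, 2L)] <- a1
  tab[, seq(2L, 2L * n_loci, 2L)] <- 2L - a1
  genotype_matrix(tab, rep(seq_len(n_loci), each = 2L),
                  allow_monomorphic = TRUE)
}

# exhaustive-search oracle: best classification log-likelihood over all
# assignments of N individuals to K = 2 non-empty groups, with
# alpha-smoothed ML frequencies (the quantity the EM maximises)
brute_force_best_ll <- function(x, alpha = 1e-6) {
  N <- n_ind(x)
  best <- -Inf
  for (code in seq_len(2^N - 2L)) {
    g <- as.integer(intToBits(code))[seq_len(N)] + 1L
    if (length(unique(g)) < 2L) next
    f <- estimate_frequencies(x, g, 2L, alpha)
    best <- max(best, total_loglik(x, g, f))
  }
  best
}

# straight-from-definition Weir & Cockerham (1984) multilocus theta,
# written with explicit scalar loops as an independent cross-check
wc_theta_direct <- function(x, labels) {
  pops <- unique(labels)
  sum_a <- 0
  sum_abc <- 0
  for (j in seq_len(n_loci(x))) {
    cols <- which(x$loci == j)
    for (col in cols) {
      n_i <- c(); p_i <- c(); h_i <- c()
      for (pop in pops) {
        idx <- which(labels == pop & !x$missing[, j])
        if (!length(idx)) next
        n_i <- c(n_i, length(idx))
        p_i <- c(p_i, sum(x$tab[idx, col]) / (2 * length(idx)))
        h_i <- c(h_i, sum(x$tab[idx, col] == 1L) / length(idx))
      }
      r <- length(n_i)
      if (r < 2) next
      nbar <- sum(n_i) / r
      nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
      pbar <- sum(n_i * p_i) / (r * nbar)
      if (pbar <= 0 || pbar >= 1 || nc <= 0) next
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      sum_a <- sum_a + a
      sum_abc <- sum_abc + a + b + cc
    }
  }
  sum_a / sum_abc
}

# build an allele_freqs matrix directly from numbers (tests only)
freqs2 <- function(f, loci) {
  structure(f, loci = as.integer(loci), alpha = 0,
            class = c("allele_freqs", "matrix"))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
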