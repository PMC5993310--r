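# one biallelic locus, four diploid genotypes (2,0),(1,1),(1,1),(0,2)
toy4 <- genotype_matrix(rbind(c(2L, 0L), c(1L, 1L), c(1L, 1L), c(0L, 2L)),
                        c(1L, 1L))

test_that("allele frequencies are ML relative frequencies, with optional smoothing", {
  f <- estimate_frequencies(toy4, rep(1L, 4L), alpha = 0)
  expect_equal(unname(f[1L, ]), c(0.5, 0.5))

  one <- toy4[1L]
  f1 <- estimate_frequencies(one, 1L, alpha = 0)
  expect_equal(unname(f1[1L, ]), c(1, 0))

  fs <- estimate_frequencies(one, 1L, alpha = 1e-6)
  expect_equal(unname(fs[1L, ]),
               c((2 + 1e-6) / (2 + 2e-6), 1e-6 / (2 + 2e-6)))

  # rows sum to 1 within each locus block
  sim <- simulate_populations(3, 10, 20, 0.3, seed = 2)
  f3 <- estimate_frequencies(sim$genotypes, rep(1:3, each = 10), alpha = 1e-6)
  sums <- t(rowsum(t(f3), sim$genotypes$loci))
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(f3 > 0))
})

test_that("missing genotypes are excluded from frequency denominators", {
  tab <- rbind(c(2L, 0L, 0L, 0L), c(1L, 1L, 2L, 0L))
  g <- genotype_matrix(tab, c(1L, 1L, 2L, 2L))
  f <- estimate_frequencies(g, c(1L, 1L), alpha = 0)
  expect_equal(unname(f[1L, ]), c(0.75, 0.25, 1, 0)) # locus 2: one genotype only

  # a group observed nowhere is degenerate
  g2 <- genotype_matrix(rbind(c(2L, 0L), c(0L, 0L)), c(1L, 1L))
  expect_error(estimate_frequencies(g2, c(1L, 2L), alpha = 0), "degenerate")
})

test_that("genotype log-likelihood is the multinomial HW mass, additive over loci", {
  het <- genotype_matrix(rbind(c(1L, 1L)), c(1L, 1L))
  f <- estimate_frequencies(toy4, rep(1L, 4L), alpha = 0) # (0.5, 0.5)
  expect_equal(as.numeric(genotype_loglik(het, f)[1L, 1L]), log(0.5)) # 2 * 0.5 * 0.5
  hom <- genotype_matrix(rbind(c(2L, 0L)), c(1L, 1L))
  expect_equal(as.numeric(genotype_loglik(hom, f)[1L, 1L]), log(0.25))

  # two independent identical loci: log-likelihoods add
  het2 <- genotype_matrix(rbind(c(1L, 1L, 1L, 1L)), c(1L, 1L, 2L, 2L))
  f2 <- freqs2(matrix(0.5, 1L, 4L), c(1L, 1L, 2L, 2L))
  expect_equal(as.numeric(genotype_loglik(het2, f2)[1L, 1L]), 2 * log(0.5))

  # Hardy-Weinberg proportions recovered exactly for p = 0.3
  p <- 0.3
  fp <- freqs2(matrix(c(p, 1 - p), 1L), c(1L, 1L))
  expect_equal(as.numeric(exp(genotype_loglik(het, fp)[1L, 1L])), 2 * p * (1 - p))
  expect_equal(as.numeric(exp(genotype_loglik(hom, fp)[1L, 1L])), p^2)

  expect_error(genotype_loglik(het, f2), "mismatch")
})

test_that("total log-likelihood sums assigned-group entries and ignores labels", {
  f <- estimate_frequencies(toy4, rep(1L, 4L), alpha = 0)
  expect_equal(total_loglik(toy4, rep(1L, 4L), f),
               log(0.25) + log(0.5) + log(0.5) + log(0.25))

  # permuting group labels together in assignment and frequencies is a no-op
  g <- c(1L, 1L, 2L, 2L)
  f2 <- estimate_frequencies(toy4, g, 2L, alpha = 1e-6)
  ll12 <- total_loglik(toy4, g, f2)
  perm <- c(2L, 2L, 1L, 1L)
  fperm <- f2[c(2L, 1L), ]
  fperm <- freqs2(fperm, attr(f2, "loci"))
  expect_equal(total_loglik(toy4, perm, fperm), ll12)

  one <- toy4[2L]
  f1 <- estimate_frequencies(one, 1L, alpha = 0)
  expect_equal(total_loglik(one, 1L, f1),
               as.numeric(genotype_loglik(one, f1)[1L, 1L]))
})

test_that("membership probabilities are stable standardised likelihoods", {
  expect_equal(membership_probabilities(rbind(c(-1, -1)))[1L, ], c(0.5, 0.5),
               ignore_attr = TRUE)
  # shift invariance
  ll <- rbind(c(-3, -5, -4), c(-100, -90, -95))
  expect_equal(membership_probabilities(ll),
               membership_probabilities(ll + 123.4))
  # extreme magnitudes: computed in the log domain
  m <- membership_probabilities(rbind(c(-1000, -1001)))
  expect_equal(m[1L, ], c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               ignore_attr = TRUE, tolerance = 1e-12)
  # rows sum to one
  expect_true(all(abs(rowSums(membership_probabilities(ll)) - 1) < 1e-12))
  expect_error(membership_probabilities(rbind(c(-Inf, -Inf))), "undefined")
})

test_that("alpha = 0 frequencies maximise the likelihood for fixed assignments", {
  # single-locus instance: compare with a grid over the frequency simplex
  x <- genotype_matrix(rbind(c(2L, 0L), c(1L, 1L), c(2L, 0L)), c(1L, 1L))
  f_ml <- estimate_frequencies(x, rep(1L, 3L), alpha = 0)
  ll_ml <- total_loglik(x, rep(1L, 3L), f_ml)
  for (p in seq(0.01, 0.99, by = 0.01)) {
    fp <- freqs2(matrix(c(p, 1 - p), 1L), c(1L, 1L))
    expect_lte(total_loglik(x, rep(1L, 3L), fp), ll_ml + 1e-12)
  }
})
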