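test_that("undifferentiated populations show near-zero Fst", {
  sim <- simulate_populations(2, 100, 300, fst = 0, seed = 1)
  expect_lt(abs(sim$realized_fst), 0.01)
  # fst = 0 collapses the Beta to the ancestral frequencies exactly
  expect_equal(sim$pop_freqs[1, ], sim$pop_freqs[2, ])
})

test_that("realized Fst tracks the Balding-Nichols target and is monotone", {
  targets <- c(0.05, 0.2, 0.6)
  means <- sapply(targets, function(f) {
    mean(sapply(1:8, function(s)
      simulate_populations(2, 100, 400, f, seed = s)$realized_fst))
  })
  expect_true(all(diff(means) > 0))
  expect_gt(means[2], 0.15)
  expect_lt(means[2], 0.25)
})

test_that("stepping-stone populations are spatially autocorrelated", {
  sim <- simulate_populations(8, 5, 400, 0.3, model = "stepping_stone",
                              seed = 4)
  d_adjacent <- mean(abs(sim$pop_freqs[1, ] - sim$pop_freqs[2, ]))
  d_far <- mean(abs(sim$pop_freqs[1, ] - sim$pop_freqs[8, ]))
  expect_lt(d_adjacent, d_far)
})

test_that("simulation output is reproducible under a fixed seed and valid", {
  s1 <- simulate_populations(3, 10, 50, 0.2, seed = 99)
  s2 <- simulate_populations(3, 10, 50, 0.2, seed = 99)
  expect_identical(s1$genotypes$tab, s2$genotypes$tab)
  expect_identical(s1$labels, s2$labels)
  # every locus block sums to the ploidy
  sums <- t(rowsum(t(s1$genotypes$tab), s1$genotypes$loci))
  expect_true(all(sums == 2L))
})

test_that("hybridize draws one gamete per parent pool", {
  n_loci <- 30L
  pA <- make_separable(5L, n_loci)[1:5]
  pB <- make_separable(5L, n_loci)[6:10]
  f1 <- hybridize(pA, pB, 50L, seed = 1)
  expect_true(all(f1$tab[, seq(1L, 2L * n_loci, 2L)] == 1L)) # all heterozygous

  # BC1 toward A: half (2,0), half (1,1) per locus in expectation
  bc1 <- hybridize(f1, pA, 400L, seed = 2)
  a1 <- bc1$tab[, seq(1L, 2L * n_loci, 2L)]
  expect_true(all(a1 >= 1L)) # allele 1 guaranteed from the fixed parent
  prop_het <- mean(a1 == 1L)
  expect_gt(prop_het, 0.45)
  expect_lt(prop_het, 0.55)

  # BC2 toward A from fixed parents: expected allele-1 frequency 1 - 1/2^3
  bc1_small <- hybridize(f1, pA, 200L, seed = 3)
  bc2 <- hybridize(bc1_small, pA, 400L, seed = 4)
  freq1 <- mean(bc2$tab[, seq(1L, 2L * n_loci, 2L)]) / 2
  expect_equal(freq1, 0.875, tolerance = 0.02)

  expect_error(hybridize(pA, make_separable(5L, 10L), 5L), "share loci")
})

test_that("hybrid datasets carry the documented class structure", {
  d <- build_hybrid_dataset(n_loci = 40, fst = 0.3, seed = 5)
  expect_equal(n_ind(d$genotypes), 250L)
  expect_equal(as.vector(table(d$labels)), c(100L, 100L, 10L, 10L, 10L, 10L, 10L))
  expect_equal(levels(d$labels),
               c("P1", "P2", "F1", "BC1-P1", "BC1-P2", "BC2-P1", "BC2-P2"))

  plain <- build_hybrid_dataset(n_loci = 40, fst = 0.3, n_parents = 20,
                                n_per_class = 0, seed = 5)
  expect_equal(n_ind(plain$genotypes), 40L)
  expect_equal(levels(plain$labels), c("P1", "P2"))

  d2 <- build_hybrid_dataset(n_loci = 40, fst = 0.3, seed = 5)
  expect_identical(d$genotypes$tab, d2$genotypes$tab)
})

test_that("Weir-Cockerham theta behaves at the extremes and matches the definition", {
  x <- make_separable(20L, 30L)
  labels <- rep(1:2, each = 20L)
  expect_gt(weir_cockerham_fst(x, labels), 0.97)

  # identical populations split in two: theta within small-sample noise of 0
  sim <- simulate_populations(1, 40, 200, 0, seed = 3)
  theta0 <- weir_cockerham_fst(sim$genotypes, rep(1:2, 20L))
  expect_gt(theta0, -0.05)
  expect_lt(theta0, 0.05)

  # dual-implementation oracle on random instances, including missing data
  for (s in 1:10) {
    sim <- simulate_populations(3, 8, 15, 0.3, seed = s)
    x <- sim$genotypes
    set.seed(s)
    drop <- cbind(sample(n_ind(x), 5), sample(n_loci(x), 5, replace = TRUE))
    for (r in seq_len(nrow(drop))) {
      x$tab[drop[r, 1], x$loci == drop[r, 2]] <- 0L
    }
    x <- genotype_matrix(x$tab, x$loci, x$ploidy, allow_monomorphic = TRUE)
    expect_equal(weir_cockerham_fst(x, sim$labels),
                 wc_theta_direct(x, sim$labels), tolerance = 1e-9)
  }

  mono <- genotype_matrix(matrix(c(2L, 0L, 2L, 0L), 2, byrow = TRUE),
                          c(1L, 1L), allow_monomorphic = TRUE)
  expect_warning(theta <- weir_cockerham_fst(mono, 1:2), "undefined")
  expect_true(is.nan(theta))
})
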