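test_that("genotype_matrix validates its invariants on construction", {
  tab <- rbind(c(2L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L))
  g <- genotype_matrix(tab, c(1L, 1L, 2L, 2L))
  expect_s3_class(g, "genotype_matrix")
  expect_equal(n_ind(g), 2L)
  expect_equal(n_loci(g), 2L)
  expect_equal(n_alleles(g), 4L)
  # all-zero block is a missing genotype
  expect_true(g$missing[2L, 2L])
  expect_false(any(g$missing[1L, ]))

  # a non-missing locus block must sum to the ploidy
  bad <- rbind(c(2L, 1L, 1L, 1L))
  expect_error(genotype_matrix(bad, c(1L, 1L, 2L, 2L)), "sum to 3")

  # monomorphic loci need the explicit flag
  expect_error(genotype_matrix(rbind(c(2L, 1L, 1L)), c(1L, 2L, 2L)),
               "monomorphic")
  expect_s3_class(genotype_matrix(rbind(c(2L, 1L, 1L)), c(1L, 2L, 2L),
                                  allow_monomorphic = TRUE),
                  "genotype_matrix")
})

test_that("genepop reader transcribes genotypes, missing codes and POP blocks", {
  path <- write_lines_tmp(c("toy data", "locA", "locB", "POP",
                            "i1 , 0101 0102", "i2 , 0102 0000"))
  g <- read_genepop(path)
  expect_equal(unname(g$tab[1L, ]), c(2L, 0L, 1L, 1L))
  expect_equal(unname(g$tab[2L, ]), c(1L, 1L, 0L, 0L))
  expect_true(g$missing[2L, 2L])
  expect_equal(g$locus_names, c("locA", "locB"))
  expect_equal(g$ids, c("i1", "i2"))

  # 3 POP blocks of 4 individuals each -> N = 12, three prior labels of 4
  blocks <- unlist(lapply(1:3, function(b) {
    c("POP", paste0("p", b, "_", 1:4, " , 010", c(1, 2, 1, 2),
      " 020", c(2, 1, 2, 1)))
  }))
  path3 <- write_lines_tmp(c("t", "l1,l2", blocks))
  g3 <- read_genepop(path3)
  expect_equal(n_ind(g3), 12L)
  expect_equal(as.vector(table(attr(g3, "pop"))), c(4L, 4L, 4L))

  # errors name the offending line / the width problem
  expect_error(read_genepop(write_lines_tmp(
    c("t", "l1", "POP", "no_comma_here 0101"))), "line 4")
  expect_error(read_genepop(write_lines_tmp(
    c("t", "l1,l2", "POP", "i1 , 0101 001001"))), "width")
})

test_that("genepop writer round-trips through the reader", {
  sim <- simulate_populations(n_pops = 2, n_per_pop = 8, n_loci = 12,
                              fst = 0.3, seed = 7)
  # anchor both alleles at every locus so the observed universe is complete
  x <- rbind_genotypes(sim$genotypes, make_separable(1L, 12L))
  path <- tempfile(fileext = ".gen")
  write_genepop(x, path)
  back <- read_genepop(path)
  expect_equal(unname(back$tab), unname(x$tab))
  expect_equal(back$missing, x$missing, ignore_attr = TRUE)
})

test_that("structure reader handles both dialects and missing codes", {
  # two-row diploid dialect: alleles 1 then 2 at locus 1 -> counts (1,1)
  g <- read_structure(write_lines_tmp(c("i1 1 3", "i1 2 -9",
                                        "i2 1 3", "i2 1 4")))
  expect_equal(unname(g$tab[1L, 1:2]), c(1L, 1L))
  expect_true(g$missing[1L, 2L])
  expect_equal(unname(g$tab[2L, ]), c(2L, 0L, 1L, 1L))

  # one-row dialect, adjacent columns per locus
  g1 <- read_structure(write_lines_tmp(c("i1 1 2 3 3", "i2 1 1 3 4")),
                       one_row_per_individual = TRUE)
  expect_equal(unname(g1$tab[1L, ]), c(1L, 1L, 2L, 0L))
  expect_equal(n_loci(g1), 2L)

  # row count must divide by ploidy in the two-row dialect
  expect_error(read_structure(write_lines_tmp(c("i1 1", "i1 2", "i2 1"))),
               "divisible")
})

test_that("structure writer round-trips a simulated matrix", {
  sim <- simulate_populations(n_pops = 1, n_per_pop = 5, n_loci = 3,
                              fst = 0, seed = 3)
  x <- rbind_genotypes(sim$genotypes, make_separable(1L, 3L))
  path <- tempfile()
  write_structure(x, path)
  back <- read_structure(path)
  expect_equal(unname(back$tab), unname(x$tab))
  expect_equal(back$ids, x$ids)
})

test_that("counts CSV reads the documented dialect and round-trips", {
  path <- write_lines_tmp(c("id,l1.1,l1.2,l2.1,l2.2", "ind1,1,1,2,0"),
                          ext = ".csv")
  g <- read_counts_csv(path)
  expect_equal(unname(g$tab[1L, ]), c(1L, 1L, 2L, 0L))

  # write -> read identity on a random simulated matrix with missing data
  sim <- simulate_populations(n_pops = 2, n_per_pop = 5, n_loci = 20,
                              fst = 0.2, seed = 11)
  x <- sim$genotypes
  x$tab[3L, 1:2] <- 0L # knock out one genotype
  x <- genotype_matrix(x$tab, x$loci, x$ploidy, ids = x$ids,
                       locus_names = x$locus_names,
                       allele_names = x$allele_names,
                       allow_monomorphic = TRUE)
  out <- tempfile(fileext = ".csv")
  write_counts_csv(x, out)
  back <- read_counts_csv(out, allow_monomorphic = TRUE)
  expect_equal(back$tab, x$tab, ignore_attr = TRUE)
  expect_equal(back$missing, x$missing, ignore_attr = TRUE)
  expect_equal(back$locus_names, x$locus_names)
  expect_equal(back$allele_names, x$allele_names)

  # a cell block summing to 3 with ploidy 2 is a validation error naming (i,j)
  bad <- write_lines_tmp(c("id,l1.1,l1.2", "ind1,2,1"), ext = ".csv")
  expect_error(read_counts_csv(bad), "individual 1.*locus 1")
})

test_that("vcf reader ingests biallelic GT and skips other sites", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
           "1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
           "1\t200\t.\tG\tC,A\t.\tPASS\t.\tGT\t0/1\t0/2",
           "1\t300\t.\tC\tG\t.\tPASS\t.\tGT\t0/0\t./.")
  path <- write_lines_tmp(vcf, ext = ".vcf")
  expect_message(g <- read_vcf_biallelic(path), "skipped 1")
  expect_equal(n_loci(g), 2L)
  expect_equal(attr(g, "n_skipped"), 1L)
  expect_equal(unname(g$tab[1L, ]), c(1L, 1L, 2L, 0L)) # s1: 0/1 then 0/0
  expect_equal(unname(g$tab[2L, ]), c(0L, 2L, 0L, 0L)) # s2: 1/1 then ./.
  expect_true(g$missing[2L, 2L])
})
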