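#' Simulate differentiated populations of biallelic genotypes
#'
#' Generates `n_pops` random-mating populations of diploid (or `ploidy`-oid)
#' individuals genotyped at `n_loci` biallelic SNPs, with among-population
#' differentiation controlled by `fst` under the Balding-Nichols model:
#' ancestral allele frequencies are drawn uniformly on
#' `[maf_floor, 1 - maf_floor]`, and each population's frequency is a Beta
#' draw `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral value `p` with
#' `F = fst`. Under the `"island"` model every population is perturbed
#' independently from the ancestor (all-to-all migration analogue); under
#' `"stepping_stone"` populations are drawn sequentially along a 1-D chain,
#' each perturbed from its neighbour with `F = fst / 2`, producing spatial
#' autocorrelation of allele frequencies. Genotypes are multinomial
#' Hardy-Weinberg draws from the population frequencies.
#'
#' @param n_pops number of populations (>= 1; >= 2 for clustering scenarios).
#' @param n_per_pop individuals per population (default 100).
#' @param n_loci number of biallelic loci (default 300).
#' @param fst target differentiation in `[0, 1)`; `fst = 0` makes all
#'   populations share the ancestral frequencies exactly.
#' @param model `"island"` or `"stepping_stone"` migration topology.
#' @param ploidy allele copies per individual per locus (default 2).
#' @param maf_floor minimum ancestral minor-allele frequency (default 0.05).
#' @param seed optional RNG seed.
#' @return A list of class `pop_sim`: `genotypes` (a [genotype_matrix]),
#'   `labels` (true population of each individual), `realized_fst`
#'   (multilocus Weir-Cockerham estimate; `NA` if `n_pops < 2`),
#'   `ancestral_freqs`, and `pop_freqs` (n_pops x n_loci allele-1
#'   frequencies).
#' @export
simulate_populations <- function(n_pops = 2L, n_per_pop = 100L,
                                 n_loci = 300L, fst = 0.2,
                                 model = c("island", "stepping_stone"),
                                 ploidy = 2L, maf_floor = 0.05,
                                 seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_pops >= 1L, n_per_pop >= 1L, n_loci >= 1L,
            fst >= 0, fst < 1, maf_floor >= 0, maf_floor < 0.5)
  with_seed(seed, {
    p_anc <- stats::runif(n_loci, maf_floor, 1 - maf_floor)
    pf <- matrix(0, n_pops, n_loci)
    if (model == "island") {
      for (k in seq_len(n_pops)) pf[k, ] <- bn_draw(p_anc, fst)
    } else {
      prev <- p_anc
      for (k in seq_len(n_pops)) {
        pf[k, ] <- bn_draw(prev, fst / 2)
        prev <- pf[k, ]
      }
    }
    N <- n_pops * n_per_pop
    labels <- rep(paste0("pop", seq_len(n_pops)), each = n_per_pop)
    a1 <- matrix(0L, N, n_loci)
    for (k in seq_len(n_pops)) {
      rows <- seq.int((k - 1L) * n_per_pop + 1L, k * n_per_pop)
      a1[rows, ] <- matrix(
        stats::rbinom(n_per_pop * n_loci, ploidy, rep(pf[k, ], each = n_per_pop)),
        n_per_pop, n_loci)
    }
    tab <- matrix(0L, N, 2L * n_loci)
    tab[, seq(1L, 2L * n_loci, by = 2L)] <- a1
    tab[, seq(2L, 2L * n_loci, by = 2L)] <- ploidy - a1
    g <- genotype_matrix(tab, rep(seq_len(n_loci), each = 2L), ploidy = ploidy,
                         allele_names = rep(c("1", "2"), n_loci),
                         allow_monomorphic = TRUE)
    realized <- if (n_pops >= 2L && ploidy == 2L) {
      suppressWarnings(weir_cockerham_fst(g, labels))
    } else NA_real_
    structure(list(genotypes = g, labels = labels, realized_fst = realized,
                   ancestral_freqs = p_anc, pop_freqs = pf,
                   model = model, fst_target = fst),
              class = "pop_sim")
  })
}

# Balding-Nichols perturbation of allele frequencies p with divergence F
bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  shape1 <- p * (1 - F) / F
  shape2 <- (1 - p) * (1 - F) / F
  out <- stats::rbeta(length(p), shape1, shape2)
  # Beta draws can hit 0/1 exactly when shapes are tiny; keep loci usable
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

#' @export
print.pop_sim <- function(x, ...) {
  cat(sprintf("pop_sim: %d populations x %d individuals, %d loci (%s model)\n",
              length(unique(x$labels)),
              length(x$labels) / length(unique(x$labels)),
              length(x$ancestral_freqs), x$model))
  cat(sprintf("  target Fst %.3f, realized Weir-Cockerham Fst %.3f\n",
              x$fst_target, x$realized_fst))
  invisible(x)
}

#' Simulate hybrids between two genotype pools
#'
#' Each hybrid receives, at every locus, one gamete allele drawn from the
#' empirical allele frequencies of `parent_a` and one from those of
#' `parent_b` (population-level gamete sampling, not tracked parent pairs).
#' Chaining calls produces backcrosses: `hybridize(f1, parent_a, n)` gives
#' first-generation backcrosses toward A, and so on.
#'
#' @param parent_a,parent_b diploid [genotype_matrix] objects over the same
#'   loci.
#' @param n number of hybrids to generate.
#' @param seed optional RNG seed.
#' @return A diploid [genotype_matrix] of `n` hybrids.
#' @export
hybridize <- function(parent_a, parent_b, n, seed = NULL) {
  stopifnot(inherits(parent_a, "genotype_matrix"),
            inherits(parent_b, "genotype_matrix"))
  if (parent_a$ploidy != 2L || parent_b$ploidy != 2L) {
    stop("hybridize() requires diploid parents")
  }
  if (!identical(parent_a$loci, parent_b$loci) ||
      !identical(parent_a$allele_names, parent_b$allele_names)) {
    stop("parents do not share loci/allele universes")
  }
  fA <- group_freq_vector(parent_a, rep(TRUE, n_ind(parent_a)), 0)
  fB <- group_freq_vector(parent_b, rep(TRUE, n_ind(parent_b)), 0)
  loci <- parent_a$loci
  with_seed(seed, {
    tab <- matrix(0L, n, length(loci))
    for (j in seq_len(max(loci))) {
      cols <- which(loci == j)
      ga <- sample.int(length(cols), n, replace = TRUE, prob = fA[cols])
      gb <- sample.int(length(cols), n, replace = TRUE, prob = fB[cols])
      for (i in seq_len(n)) {
        tab[i, cols[ga[i]]] <- tab[i, cols[ga[i]]] + 1L
        tab[i, cols[gb[i]]] <- tab[i, cols[gb[i]]] + 1L
      }
    }
    genotype_matrix(tab, loci, ploidy = 2L,
                    ids = paste0("hyb", seq_len(n)),
                    locus_names = parent_a$locus_names,
                    allele_names = parent_a$allele_names,
                    allow_monomorphic = TRUE)
  })
}

#' Simulate a two-population dataset with hybrid classes
#'
#' Builds the standard hybrid-detection benchmark: two parental populations
#' P1 and P2 at a controlled Fst, plus F1 hybrids (P1 x P2), first-generation
#' backcrosses (BC1-P1 = F1 x P1, BC1-P2 = F1 x P2) and second-generation
#' backcrosses (BC2-P1 = BC1-P1 x P1, BC2-P2 = BC1-P2 x P2). Defaults give
#' 100 individuals per parental population and 10 per hybrid class (50
#' hybrids, 250 individuals in total).
#'
#' @param n_loci number of biallelic loci (default 300).
#' @param fst target parental differentiation (default 0.4).
#' @param n_parents individuals per parental population (default 100).
#' @param n_per_class individuals per hybrid class (default 10); 0 gives a
#'   plain two-population dataset.
#' @param model migration topology for the parental simulation.
#' @param maf_floor minimum ancestral minor-allele frequency.
#' @param seed optional RNG seed.
#' @return A list of class `pop_sim` with `genotypes`, `labels` (factor with
#'   levels P1, P2, F1, BC1-P1, BC1-P2, BC2-P1, BC2-P2), and `realized_fst`
#'   (between the parental populations).
#' @export
build_hybrid_dataset <- function(n_loci = 300L, fst = 0.4, n_parents = 100L,
                                 n_per_class = 10L,
                                 model = "island", maf_floor = 0.05,
                                 seed = NULL) {
  with_seed(seed, {
    sim <- simulate_populations(n_pops = 2L, n_per_pop = n_parents,
                                n_loci = n_loci, fst = fst, model = model,
                                maf_floor = maf_floor)
    p1 <- sim$genotypes[sim$labels == "pop1"]
    p2 <- sim$genotypes[sim$labels == "pop2"]
    if (n_per_class == 0L) {
      out <- list(genotypes = sim$genotypes,
                  labels = factor(ifelse(sim$labels == "pop1", "P1", "P2"),
                                  levels = c("P1", "P2")),
                  realized_fst = sim$realized_fst,
                  fst_target = fst, model = model,
                  ancestral_freqs = sim$ancestral_freqs)
      class(out) <- "pop_sim"
      return(out)
    }
    f1 <- hybridize(p1, p2, n_per_class)
    bc1_p1 <- hybridize(f1, p1, n_per_class)
    bc1_p2 <- hybridize(f1, p2, n_per_class)
    bc2_p1 <- hybridize(bc1_p1, p1, n_per_class)
    bc2_p2 <- hybridize(bc1_p2, p2, n_per_class)
    lev <- c("P1", "P2", "F1", "BC1-P1", "BC1-P2", "BC2-P1", "BC2-P2")
    labels <- factor(rep(lev, c(n_parents, n_parents, rep(n_per_class, 5L))),
                     levels = lev)
    out <- list(
      genotypes = rbind_genotypes(p1, p2, f1, bc1_p1, bc1_p2, bc2_p1, bc2_p2),
      labels = labels, realized_fst = sim$realized_fst,
      fst_target = fst, model = model,
      ancestral_freqs = sim$ancestral_freqs)
    class(out) <- "pop_sim"
    out
  })
}

#' Multilocus Weir-Cockerham Fst
#'
#' The Weir & Cockerham (1984) theta estimator of among-population
#' differentiation for diploid data, computed per allele per locus as
#' variance components (a: among populations, b: among individuals within
#' populations, c: within individuals) and combined as the multilocus
#' ratio of sums `sum(a) / sum(a + b + c)`. Missing genotypes are excluded
#' per locus; monomorphic loci contribute zero to both sums.
#'
#' @param x a diploid [genotype_matrix].
#' @param labels population labels, length N, with at least two populations.
#' @return The multilocus theta estimate (scalar; `NaN` with a warning if
#'   every locus is monomorphic).
#' @export
weir_cockerham_fst <- function(x, labels) {
  stopifnot(inherits(x, "genotype_matrix"), length(labels) == n_ind(x))
  if (x$ploidy != 2L) stop("Weir-Cockerham theta is defined here for diploids")
  pops <- unique(labels)
  r_all <- length(pops)
  if (r_all < 2L) stop("need at least 2 labelled populations")
  num <- 0
  den <- 0
  for (j in seq_len(n_loci(x))) {
    cols <- which(x$loci == j)
    ok <- !x$missing[, j]
    n_i <- vapply(pops, function(p) sum(ok & labels == p), numeric(1L))
    use <- n_i > 0
    r <- sum(use)
    if (r < 2L) next
    n_i <- n_i[use]
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    for (cc in cols) {
      cnt <- x$tab[, cc]
      p_i <- vapply(pops[use], function(p) {
        idx <- ok & labels == p
        sum(cnt[idx]) / (2 * sum(idx))
      }, numeric(1L))
      h_i <- vapply(pops[use], function(p) {
        idx <- ok & labels == p
        mean(cnt[idx] == 1L)
      }, numeric(1L))
      pbar <- sum(n_i * p_i) / (r * nbar)
      if (pbar <= 0 || pbar >= 1) next
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      c_ <- hbar / 2
      num <- num + a
      den <- den + a + b + c_
    }
  }
  if (den == 0) {
    warning("Fst undefined: no polymorphic locus")
    return(NaN)
  }
  num / den
}
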