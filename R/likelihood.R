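#' Maximum-likelihood allele frequencies per group
#'
#' Estimates group allele frequencies as the relative frequencies of alleles
#' among the individuals of each group, optionally smoothed with a
#' pseudo-count `alpha` added to every allele count. `alpha = 0` gives the
#' plain maximum-likelihood estimate; a small positive `alpha` keeps every
#' frequency strictly positive so log-likelihoods stay finite when a group
#' happens to lose an allele. Missing genotypes contribute nothing to either
#' numerator or denominator.
#'
#' @param x a [genotype_matrix].
#' @param groups integer vector of group assignments in `1..K`.
#' @param K number of groups (default `max(groups)`).
#' @param alpha non-negative pseudo-count per allele (default 0).
#' @return A K x P matrix of class `allele_freqs`, rows summing to 1 within
#'   each locus block; attributes `loci`, `alpha`, `group_labels`.
#' @export
estimate_frequencies <- function(x, groups, K = max(groups), alpha = 0) {
  stopifnot(length(groups) == n_ind(x), alpha >= 0)
  groups <- as.integer(groups)
  if (any(groups < 1L | groups > K)) stop("group indices must lie in 1..K")
  J <- n_loci(x)
  counts <- matrix(0, K, n_alleles(x))
  agg <- rowsum(x$tab, groups)
  counts[as.integer(rownames(agg)), ] <- agg
  obs_den <- t(rowsum(t(counts), x$loci)) # K x J observed allele copies
  empty <- which(rowSums(obs_den) == 0)
  if (length(empty)) {
    stop("group ", empty[1L],
         " has zero non-missing observations at every locus (degenerate group)")
  }
  num <- counts + alpha
  den <- t(rowsum(t(num), x$loci))
  den[den == 0] <- 1 # alpha = 0 and a locus unobserved in a group: zero row
  f <- num / den[, x$loci, drop = FALSE]
  freqs(f, x$loci, alpha, rownames = paste0("grp", seq_len(K)))
}

freqs <- function(f, loci, alpha, rownames = NULL) {
  if (!is.null(rownames)) rownames(f) <- rownames
  structure(f, loci = loci, alpha = alpha, class = c("allele_freqs", "matrix"))
}

#' Per-individual, per-group genotype log-likelihoods
#'
#' Under random mating, the probability of a genotype at one locus is the
#' multinomial mass of drawing its `ploidy` allele copies from the group's
#' allele frequencies; loci are assumed independent, so the per-individual
#' log-likelihood is the sum of per-locus log masses over non-missing loci.
#' The multinomial coefficient is included, making each entry a true
#' log-probability (it is constant across groups, so memberships are
#' unaffected by the convention).
#'
#' @param x a [genotype_matrix].
#' @param f an `allele_freqs` matrix (groups x alleles), e.g. from
#'   [estimate_frequencies()].
#' @return An N x K matrix of log-likelihoods.
#' @export
genotype_loglik <- function(x, f) {
  if (ncol(f) != n_alleles(x)) {
    stop("allele universe mismatch: frequencies have ", ncol(f),
         " columns, genotypes ", n_alleles(x))
  }
  logf <- log(f)
  logf[!is.finite(logf)] <- -1e308 # 0 * logf must stay 0 in the product below
  # log multinomial coefficient per individual, over non-missing loci
  n_obs_loci <- n_loci(x) - rowSums(x$missing)
  coefs <- unname(n_obs_loci * lgamma(x$ploidy + 1) -
                    rowSums(lgamma(x$tab + 1)))
  ll <- x$tab %*% t(logf) + coefs
  rownames(ll) <- x$ids
  colnames(ll) <- rownames(f)
  ll
}

#' Log-likelihood of a clustering solution
#'
#' The classification log-likelihood: the sum over individuals of the
#' log-probability of their genotype in their assigned group.
#'
#' @inheritParams genotype_loglik
#' @param groups integer group assignments in `1..nrow(f)`.
#' @return A scalar.
#' @export
total_loglik <- function(x, groups, f) {
  ll <- genotype_loglik(x, f)
  sum(ll[cbind(seq_len(nrow(ll)), as.integer(groups))])
}

#' Group-membership probabilities from log-likelihoods
#'
#' Standardises each individual's likelihood across groups: row `i` is
#' `exp(ll[i,]) / sum_q exp(ll[i,q])`, computed stably in the log domain.
#'
#' @param ll an N x K matrix of per-individual, per-group log-likelihoods.
#' @return An N x K probability matrix with rows summing to 1.
#' @export
membership_probabilities <- function(ll) {
  ll <- as.matrix(ll)
  mx <- apply(ll, 1L, max)
  if (any(!is.finite(mx))) {
    stop("membership undefined: an individual has -Inf log-likelihood in every group")
  }
  w <- exp(ll - mx)
  w / rowSums(w)
}
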