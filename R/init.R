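# Starting-point strategies for the EM optimiser.

#' Initial group assignments
#'
#' Three strategies for seeding the EM algorithm: `init_ward()` cuts a
#' Ward-linkage tree built on Euclidean distances between individual allele
#' frequency profiles (fully deterministic); `init_kmeans()` runs K-means on
#' PCA scores retaining a target share of the total variance; `init_random()`
#' draws uniform labels constrained so every group is non-empty (the
#' brute-force multi-start strategy).
#'
#' @param x a [genotype_matrix].
#' @param K number of groups.
#' @return An integer vector of length N with values in `1..K`.
#' @export
init_ward <- function(x, K) {
  stopifnot(K >= 1L, K <= n_ind(x))
  if (K == 1L) return(rep(1L, n_ind(x)))
  prof <- allele_profiles(x)
  hc <- stats::hclust(stats::dist(prof), method = "ward.D2")
  unname(stats::cutree(hc, k = K))
}

#' @rdname init_ward
#' @param var_retained proportion of total variance the retained principal
#'   axes must reach before K-means (default 0.9).
#' @param seed optional RNG seed for the K-means restarts.
#' @export
init_kmeans <- function(x, K, var_retained = 0.9, seed = NULL) {
  stopifnot(K >= 1L, K <= n_ind(x), var_retained > 0, var_retained <= 1)
  if (K == 1L) return(rep(1L, n_ind(x)))
  prof <- allele_profiles(x)
  pc <- stats::prcomp(prof, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_axes <- max(which(cum >= var_retained - 1e-12)[1L], 1L)
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  with_seed(seed, {
    km <- stats::kmeans(scores, centers = K, nstart = 10L, iter.max = 50L)
    unname(km$cluster)
  })
}

#' @rdname init_ward
#' @param N number of individuals (for `init_random`).
#' @export
init_random <- function(N, K, seed = NULL) {
  stopifnot(K >= 1L, K <= N)
  with_seed(seed, {
    g <- c(sample.int(K), sample.int(K, N - K, replace = TRUE))
    g[sample.int(N)]
  })
}
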