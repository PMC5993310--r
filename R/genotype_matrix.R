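#' Genotype matrix of per-individual allele counts
#'
#' The central data container of the package: an N x P integer matrix of
#' allele copy counts, where the P columns are the alleles of J loci laid out
#' locus by locus. Each individual carries exactly `ploidy` allele copies at
#' every non-missing locus; a missing genotype is recorded in `missing` and
#' its counts are all zero.
#'
#' @param tab integer matrix, individuals x alleles (counts of allele copies).
#' @param loci integer vector of length `ncol(tab)` mapping each column to its
#'   locus (values `1..J`, non-decreasing, contiguous).
#' @param ploidy number of allele copies per individual per locus (default 2).
#' @param ids individual labels (default `ind1..indN`).
#' @param locus_names locus labels (default `loc1..locJ`).
#' @param allele_names per-column allele labels within each locus.
#' @param missing optional N x J logical matrix flagging missing genotypes;
#'   by default inferred from all-zero locus blocks.
#' @param allow_monomorphic if `FALSE` (default) every locus must carry at
#'   least two allele columns; set `TRUE` for data with declared biallelic
#'   loci that may be fixed in the sample (e.g. simulated SNPs).
#'
#' @return An object of class `genotype_matrix` with elements `tab`, `loci`,
#'   `ploidy`, `ids`, `locus_names`, `allele_names`, `missing`.
#' @export
genotype_matrix <- function(tab, loci, ploidy = 2L, ids = NULL,
                            locus_names = NULL, allele_names = NULL,
                            missing = NULL, allow_monomorphic = FALSE) {
  tab <- as.matrix(tab)
  storage.mode(tab) <- "integer"
  loci <- as.integer(loci)
  ploidy <- as.integer(ploidy)
  if (length(ploidy) != 1L || is.na(ploidy) || ploidy < 1L) {
    stop("`ploidy` must be a single positive integer")
  }
  if (length(loci) != ncol(tab)) {
    stop("`loci` must have one entry per column of `tab`")
  }
  if (is.unsorted(loci)) stop("`loci` must be non-decreasing (locus-blocked columns)")
  J <- max(loci)
  if (!setequal(unique(loci), seq_len(J))) stop("`loci` must cover 1..J contiguously")
  N <- nrow(tab)
  ids <- ids %||% paste0("ind", seq_len(N))
  locus_names <- locus_names %||% paste0("loc", seq_len(J))
  if (length(locus_names) != J) stop("`locus_names` must have length J")
  if (anyDuplicated(locus_names)) stop("duplicated locus names")
  n_all <- tabulate(loci, nbins = J)
  if (!allow_monomorphic && any(n_all < 2L)) {
    stop("locus ", locus_names[which(n_all < 2L)[1L]],
         " has fewer than 2 allele columns; pass allow_monomorphic = TRUE ",
         "to accept monomorphic loci")
  }
  allele_names <- allele_names %||%
    unlist(lapply(n_all, seq_len), use.names = FALSE)
  allele_names <- as.character(allele_names)
  if (length(allele_names) != ncol(tab)) stop("`allele_names` must have length P")

  locus_sums <- t(rowsum(t(tab), loci)) # N x J
  if (is.null(missing)) {
    missing <- locus_sums == 0L
  } else {
    missing <- as.matrix(missing)
    if (!identical(dim(missing), c(N, J))) stop("`missing` must be N x J")
  }
  bad <- which(!missing & locus_sums != ploidy, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "allele counts at individual %d (%s), locus %d (%s) sum to %d, expected ploidy %d",
      bad[1L, 1L], ids[bad[1L, 1L]], bad[1L, 2L], locus_names[bad[1L, 2L]],
      locus_sums[bad[1L, , drop = FALSE]], ploidy))
  }
  if (any(missing & locus_sums != 0L)) {
    stop("missing genotypes must have all-zero allele counts")
  }
  if (any(tab < 0L)) stop("negative allele counts")

  dimnames(tab) <- list(ids, paste(locus_names[loci], allele_names, sep = "."))
  dimnames(missing) <- list(ids, locus_names)
  structure(
    list(tab = tab, loci = loci, ploidy = ploidy, ids = ids,
         locus_names = locus_names, allele_names = allele_names,
         missing = missing),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals, %d loci, %d alleles (ploidy %d)\n",
    n_ind(x), n_loci(x), n_alleles(x), x$ploidy))
  nm <- sum(x$missing)
  if (nm > 0) {
    cat(sprintf("  %d missing genotypes (%.1f%%)\n",
                nm, 100 * nm / length(x$missing)))
  }
  pop <- attr(x, "pop")
  if (!is.null(pop)) {
    cat("  prior group labels: ",
        paste(names(table(pop)), table(pop), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  out <- list(
    n_ind = n_ind(object), n_loci = n_loci(object),
    n_alleles = n_alleles(object), ploidy = object$ploidy,
    alleles_per_locus = tabulate(object$loci, nbins = n_loci(object)),
    prop_missing = mean(object$missing))
  class(out) <- "summary.genotype_matrix"
  out
}

#' @export
print.summary.genotype_matrix <- function(x, ...) {
  cat(sprintf("%d individuals x %d loci (P = %d alleles), ploidy %d\n",
              x$n_ind, x$n_loci, x$n_alleles, x$ploidy))
  cat(sprintf("alleles per locus: %s\n",
              paste(range(x$alleles_per_locus), collapse = "-")))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * x$prop_missing))
  invisible(x)
}

#' Dimensions of a genotype matrix
#'
#' `n_ind()`, `n_loci()` and `n_alleles()` return the number of individuals
#' N, loci J and total allele columns P.
#'
#' @param x a [genotype_matrix].
#' @return An integer scalar.
#' @export
n_ind <- function(x) nrow(x$tab)

#' @rdname n_ind
#' @export
n_loci <- function(x) length(x$locus_names)

#' @rdname n_ind
#' @export
n_alleles <- function(x) ncol(x$tab)

#' Subset individuals of a genotype matrix
#'
#' @param x a [genotype_matrix].
#' @param i individual index vector.
#' @param ... ignored.
#' @return A [genotype_matrix] with the selected individuals.
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  genotype_matrix(x$tab[i, , drop = FALSE], x$loci, x$ploidy,
                  ids = x$ids[i], locus_names = x$locus_names,
                  allele_names = x$allele_names,
                  missing = x$missing[i, , drop = FALSE],
                  allow_monomorphic = TRUE)
}

#' Stack genotype matrices over individuals
#'
#' All inputs must share loci, allele universes and ploidy.
#'
#' @param ... [genotype_matrix] objects.
#' @return A combined [genotype_matrix].
#' @export
rbind_genotypes <- function(...) {
  gs <- list(...)
  ref <- gs[[1L]]
  for (g in gs[-1L]) {
    if (!identical(g$loci, ref$loci) ||
        !identical(g$allele_names, ref$allele_names) ||
        !identical(g$locus_names, ref$locus_names) ||
        g$ploidy != ref$ploidy) {
      stop("genotype matrices do not share loci/alleles/ploidy")
    }
  }
  genotype_matrix(
    do.call(rbind, lapply(gs, `[[`, "tab")), ref$loci, ref$ploidy,
    ids = make.unique(unlist(lapply(gs, `[[`, "ids"))),
    locus_names = ref$locus_names, allele_names = ref$allele_names,
    missing = do.call(rbind, lapply(gs, `[[`, "missing")),
    allow_monomorphic = TRUE)
}

# individual profiles in frequency units (counts / ploidy), with missing
# genotypes mean-imputed column-wise; used by the geometric initialisers
allele_profiles <- function(x) {
  prof <- x$tab / x$ploidy
  if (any(x$missing)) {
    miss_cols <- x$missing[, x$loci, drop = FALSE] # N x P
    prof[miss_cols] <- NA_real_
    mu <- colMeans(prof, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(prof), arr.ind = TRUE)
    prof[idx] <- mu[idx[, 2L]]
  }
  prof
}
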