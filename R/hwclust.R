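#' Maximum-likelihood genetic clustering by classification EM
#'
#' Assigns individual multilocus genotypes to `k` panmictic populations by
#' maximising the Hardy-Weinberg multinomial likelihood of the clustering
#' with a hard-assignment (classification) EM algorithm: allele frequencies
#' are re-estimated within each group (expectation step), per-individual
#' group-membership probabilities are computed as standardised likelihoods,
#' and each individual is re-assigned to its most likely group (maximisation
#' step), until the log-likelihood changes by less than `tol`.
#'
#' With `hybrids` set, the model instead comprises two parental populations A
#' and B plus hybrid classes whose allele frequencies are the mixtures
#' `w * fA + (1 - w) * fB` defined by the scheme's hybridisation
#' coefficients. Only the two parental frequency sets are free parameters,
#' re-estimated each iteration from the individuals currently assigned to A
#' and B.
#'
#' Starting points: `"ward"` (default, deterministic) cuts a Ward-linkage
#' tree on individual allele-frequency profiles; `"kmeans"` clusters PCA
#' scores retaining `var_retained` of the variance; `"random"` is a
#' brute-force multi-start with `n_start` random initial partitions, keeping
#' the best final likelihood; `"user"` takes `groups` as given.
#'
#' @param x a [genotype_matrix].
#' @param k number of groups (ignored when `hybrids` is supplied).
#' @param init initialisation strategy: `"ward"`, `"kmeans"`, `"random"` or
#'   `"user"`.
#' @param hybrids optional [hybrid_scheme()] (or a numeric vector of
#'   hybridisation coefficients) switching on hybrid-class clustering.
#' @param groups user-supplied initial assignment (forces `init = "user"`);
#'   values `1..k`, or `1/2` (parental split) in hybrid mode.
#' @param n_start number of random starts when `init = "random"`.
#' @param tol convergence threshold on the change in log-likelihood between
#'   successive iterations (default 1e-10).
#' @param max_iter maximum number of EM iterations (default 100).
#' @param alpha pseudo-count smoothing of allele frequencies (default 1e-6);
#'   keeps log-likelihoods finite when a group loses an allele.
#' @param var_retained variance proportion retained by the K-means
#'   initialiser's PCA step (default 0.9).
#' @param seed optional integer seed governing all randomness of the fit.
#'
#' @return An object of class `hwclust`: a list with components
#'   `assignment` (integer groups), `groups` (factor with class labels),
#'   `memberships` (N x K probability matrix), `frequencies` (fitted
#'   `allele_freqs`), `loglik` (the maximised classification log-likelihood
#'   L'), `trace`, `n_iter`, `converged`, `n_params`, and fit metadata.
#'
#' @examples
#' sim <- simulate_populations(n_pops = 2, n_per_pop = 30, n_loci = 100,
#'                             fst = 0.3, seed = 1)
#' fit <- hwclust(sim$genotypes, k = 2)
#' fit
#' pairwise_tpr_tnr(sim$labels, fit$assignment)
#' @export
hwclust <- function(x, k = NULL, init = c("ward", "kmeans", "random", "user"),
                    hybrids = NULL, groups = NULL, n_start = 50L,
                    tol = 1e-10, max_iter = 100L, alpha = 1e-6,
                    var_retained = 0.9, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!is.null(groups)) init <- "user" else init <- match.arg(init)
  if (tol <= 0) stop("`tol` must be positive")
  N <- n_ind(x)

  scheme <- hybrids
  if (!is.null(scheme) && !inherits(scheme, "hybrid_scheme")) {
    scheme <- hybrid_scheme(scheme)
  }
  K0 <- if (is.null(scheme)) {
    if (is.null(k)) stop("`k` must be given (or supply `hybrids`)")
    as.integer(k)
  } else 2L # classes are derived; initial split is parental
  if (K0 < 1L || K0 > N) stop("`k` must lie in 1..N (N = ", N, ")")

  res <- with_seed(seed, {
    if (init == "random" && K0 > 1L) {
      best <- NULL
      for (s in seq_len(max(1L, as.integer(n_start)))) {
        g0 <- init_random(N, K0)
        cand <- em_engine(x, g0, K0, tol, max_iter, alpha, scheme)
        if (is.null(best) || cand$loglik > best$loglik) best <- cand
      }
      best
    } else {
      g0 <- switch(init,
        ward   = init_ward(x, K0),
        kmeans = init_kmeans(x, K0, var_retained = var_retained),
        random = init_ward(x, K0), # K0 == 1
        user   = {
          g <- as.integer(groups)
          if (length(g) != N || any(is.na(g)) || any(g < 1L | g > K0)) {
            stop("`groups` must be length N with values in 1..", K0)
          }
          if (length(unique(g)) != K0) {
            stop("`groups` must use every group in 1..", K0, " at least once")
          }
          g
        })
      em_engine(x, g0, K0, tol, max_iter, alpha, scheme)
    }
  })

  P <- n_alleles(x)
  J <- n_loci(x)
  K <- if (is.null(scheme)) K0 else length(scheme$w)
  labels <- if (is.null(scheme)) as.character(seq_len(K0)) else scheme$labels
  colnames(res$memberships) <- labels
  rownames(res$memberships) <- x$ids
  rownames(res$frequencies) <- labels
  n_params <- if (is.null(scheme)) K0 * (P - J) else 2L * (P - J)
  if (n_params <= 0L) {
    stop("model has no free parameters: every locus is monomorphic (P = J)")
  }
  if (!res$converged) {
    warning("EM did not converge in ", max_iter, " iterations (|dLL| >= ", tol, ")")
  }

  structure(list(
    assignment = res$groups,
    groups = factor(labels[res$groups], levels = labels),
    memberships = res$memberships,
    frequencies = res$frequencies,
    loglik = res$loglik,
    trace = res$trace,
    n_iter = res$n_iter,
    converged = res$converged,
    n_repairs = res$n_repairs,
    n_params = n_params,
    K = K, N = N, P = P, J = J, ploidy = x$ploidy,
    scheme = scheme, init = init, seed = seed,
    tol = tol, alpha = alpha, ids = x$ids,
    call = match.call()),
    class = "hwclust")
}

# the classification-EM loop; `scheme` NULL for plain clustering, else a
# hybrid_scheme whose parental classes (w = 1, w = 0) are the free parameters
em_engine <- function(x, groups, K, tol, max_iter, alpha, scheme = NULL) {
  N <- n_ind(x)
  g <- as.integer(groups)
  hybrid <- !is.null(scheme)
  if (hybrid) {
    iA <- which(scheme$w == 1)
    iB <- which(scheme$w == 0)
    Kc <- length(scheme$w)
    g <- ifelse(g == 1L, iA, iB) # parental split -> class indices
  } else {
    Kc <- K
  }

  trace <- numeric(0)
  best <- NULL
  n_repairs <- 0L
  converged <- FALSE
  ll_prev <- NA_real_

  for (iter in seq_len(max_iter)) {
    f <- if (hybrid) hybrid_class_freqs(x, g, scheme, iA, iB, alpha)
         else estimate_frequencies(x, g, Kc, alpha)
    ll <- genotype_loglik(x, f)
    m <- membership_probabilities(ll)
    g_new <- max.col(m, ties.method = "first")

    # keep required classes non-empty: re-seed an empty group with the
    # individual currently least certain of its own assignment
    need <- if (hybrid) c(iA, iB) else seq_len(Kc)
    sizes <- tabulate(g_new, Kc)
    for (k_empty in need[sizes[need] == 0L]) {
      movable <- which(tabulate(g_new, Kc)[g_new] > 1L)
      if (!length(movable)) break
      worst <- movable[which.min(apply(m[movable, , drop = FALSE], 1L, max))]
      g_new[worst] <- k_empty
      n_repairs <- n_repairs + 1L
    }

    LL <- sum(ll[cbind(seq_len(N), g_new)])
    trace <- c(trace, LL)
    if (is.null(best) || LL > best$loglik) {
      best <- list(loglik = LL, groups = g_new, frequencies = f,
                   memberships = m)
    }
    if ((!is.na(ll_prev) && abs(LL - ll_prev) < tol) ||
        identical(g_new, g)) { # stable assignment: LL can no longer change
      converged <- TRUE
      break
    }
    ll_prev <- LL
    g <- g_new
    if (Kc == 1L) { converged <- TRUE; break }
  }

  c(best, list(trace = trace, n_iter = length(trace),
               converged = converged, n_repairs = n_repairs))
}

hybrid_class_freqs <- function(x, g, scheme, iA, iB, alpha) {
  inA <- g == iA
  inB <- g == iB
  if (!any(inA) && !any(inB)) {
    stop("both parental classes are empty (degenerate input)")
  }
  fA <- group_freq_vector(x, inA, alpha)
  fB <- group_freq_vector(x, inB, alpha)
  f <- outer(scheme$w, fA) + outer(1 - scheme$w, fB)
  freqs(f, x$loci, alpha, rownames = scheme$labels)
}

group_freq_vector <- function(x, idx, alpha) {
  counts <- colSums(x$tab[idx, , drop = FALSE])
  num <- counts + alpha
  den <- rowsum(num, x$loci)[, 1L]
  den[den == 0] <- 1
  num / den[x$loci]
}

#' @export
print.hwclust <- function(x, ...) {
  kind <- if (is.null(x$scheme)) sprintf("K = %d groups", x$K)
          else sprintf("%d hybrid classes (%s)", x$K,
                       paste(levels(x$groups), collapse = ", "))
  cat(sprintf("hwclust fit: %s, %d individuals, %d loci\n", kind, x$N, x$J))
  cat(sprintf("  log-likelihood L' = %.4f  (%d free parameters)\n",
              x$loglik, x$n_params))
  cat(sprintf("  %d EM iterations, converged: %s, init: %s\n",
              x$n_iter, x$converged, x$init))
  cat("  group sizes: ",
      paste(levels(x$groups), table(x$groups), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.hwclust <- function(object, ...) {
  out <- list(
    fit = object,
    sizes = table(object$groups),
    mean_support = tapply(
      object$memberships[cbind(seq_len(object$N), object$assignment)],
      object$groups, mean),
    aic = AIC(object), aicc = AICc(object),
    bic = BIC(object), kic = KIC(object))
  class(out) <- "summary.hwclust"
  out
}

#' @export
print.summary.hwclust <- function(x, ...) {
  print(x$fit)
  cat("  mean membership probability of the assigned group, by group:\n")
  print(round(x$mean_support, 4))
  cat(sprintf("  AIC = %.2f  AICc = %.2f  BIC = %.2f  KIC = %.2f\n",
              x$aic, x$aicc, x$bic, x$kic))
  invisible(x)
}

#' @export
logLik.hwclust <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$N,
            class = "logLik")
}

#' @export
coef.hwclust <- function(object, ...) object$frequencies

#' Membership probabilities for new genotypes
#'
#' Computes standardised Hardy-Weinberg likelihoods of new genotypes under
#' the fitted group allele frequencies.
#'
#' @param object a fitted [hwclust] model.
#' @param newdata a [genotype_matrix] over the same allele universe; default
#'   is to return the fit's own membership matrix.
#' @param ... ignored.
#' @return An N x K matrix of membership probabilities.
#' @export
predict.hwclust <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$memberships)
  membership_probabilities(genotype_loglik(newdata, object$frequencies))
}

#' Simulate genotypes from a fitted clustering
#'
#' Draws multinomial Hardy-Weinberg genotypes from the fitted group allele
#' frequencies, with the fitted group sizes.
#'
#' @param object a fitted [hwclust] model.
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param ... ignored.
#' @return A list of `nsim` [genotype_matrix] objects, each with attribute
#'   `groups` giving the generating group of every individual.
#' @export
simulate.hwclust <- function(object, nsim = 1, seed = NULL, ...) {
  f <- object$frequencies
  loci <- attr(f, "loci")
  g <- object$assignment
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      tab <- matrix(0L, length(g), ncol(f))
      for (j in seq_len(max(loci))) {
        cols <- which(loci == j)
        for (i in seq_along(g)) {
          tab[i, cols] <- as.integer(
            stats::rmultinom(1L, object$ploidy, f[g[i], cols]))
        }
      }
      out <- genotype_matrix(tab, loci, ploidy = object$ploidy,
                             allow_monomorphic = TRUE)
      attr(out, "groups") <- g
      out
    })
  })
}

#' Membership composition plot
#'
#' STRUCTURE-style stacked barplot of group-membership probabilities, one
#' bar per individual.
#'
#' @param x a fitted [hwclust] model.
#' @param col colours, one per group.
#' @param sort_by_group order individuals by assigned group (default TRUE).
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.hwclust <- function(x, col = NULL, sort_by_group = TRUE, ...) {
  m <- x$memberships
  ord <- if (sort_by_group) order(x$assignment) else seq_len(nrow(m))
  col <- col %||% grDevices::hcl.colors(ncol(m), "Dark 3")
  mid <- graphics::barplot(t(m[ord, , drop = FALSE]), col = col, border = NA,
                           space = 0, names.arg = rep("", nrow(m)),
                           ylab = "membership probability",
                           xlab = "individuals", ...)
  graphics::legend("topright", legend = colnames(m), fill = col,
                   bg = "white", cex = 0.8)
  invisible(mid)
}
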