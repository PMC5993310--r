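#' Goodness-of-fit criteria for clustering solutions
#'
#' Penalised-deviance statistics comparing clustering solutions across
#' numbers of groups. With L' the maximised classification log-likelihood
#' and `k = K(P - J)` free parameters (each of the K groups estimates P - J
#' independent allele frequencies; `2(P - J)` in hybrid mode, where only the
#' two parental frequency sets are free):
#'
#' * `AIC  = -2 L' + 2 k`
#' * `AICc = -2 L' + 2 k N / (N - k - 1)` (small-sample variant)
#' * `BIC  = -2 L' + ln(N) k`
#' * `KIC  = -2 L' + 3 (k + 1)` (Kullback information criterion)
#'
#' Lower values indicate better fits. `AIC` and `BIC` for `hwclust` objects
#' come from the standard [stats::AIC()] / [stats::BIC()] generics via
#' [logLik.hwclust()]; `AICc()` and `KIC()` are generics defined here.
#'
#' @param object a fitted [hwclust] model.
#' @param ... ignored.
#' @return A scalar criterion value.
#' @name fit-criteria
NULL

#' @rdname fit-criteria
#' @export
AICc <- function(object, ...) UseMethod("AICc")

#' @rdname fit-criteria
#' @export
AICc.hwclust <- function(object, ...) {
  ic_aicc(object$loglik, object$n_params, object$N)
}

#' @rdname fit-criteria
#' @export
KIC <- function(object, ...) UseMethod("KIC")

#' @rdname fit-criteria
#' @export
KIC.hwclust <- function(object, ...) {
  -2 * object$loglik + 3 * (object$n_params + 1)
}

ic_aicc <- function(loglik, n_params, N) {
  den <- N - n_params - 1
  if (den == 0) {
    stop("AICc undefined: N - k - 1 = 0 (sample size equals the parameter ",
         "count plus one); use AIC or BIC for this model size")
  }
  if (den < 0) {
    warning("AICc small-sample correction applied outside its domain ",
            "(N - k - 1 = ", den, "); interpret with care")
  }
  -2 * loglik + 2 * n_params * N / den
}

#' Goodness-of-fit statistics from model components
#'
#' Computes the four criteria directly from a log-likelihood and the model
#' dimensions, without a fitted object: `n_params = K (P - J)` free allele
#' frequencies (`2 (P - J)` in hybrid mode, where only the two parental
#' frequency sets are estimated).
#'
#' @param loglik maximised classification log-likelihood L'.
#' @param K number of groups (classes in hybrid mode).
#' @param P total number of alleles across loci.
#' @param J number of loci.
#' @param N number of individuals.
#' @param hybrid `TRUE` for the hybrid-mode parameter count.
#' @return A one-row data frame with columns `K`, `loglik`, `n_params`,
#'   `AIC`, `AICc`, `BIC`, `KIC`.
#' @export
fit_stats <- function(loglik, K, P, J, N, hybrid = FALSE) {
  stopifnot(is.finite(loglik), K >= 1, P >= J, N >= 1)
  n_params <- if (hybrid) 2 * (P - J) else K * (P - J)
  if (n_params <= 0) stop("model has no free parameters (P = J)")
  data.frame(
    K = K, loglik = loglik, n_params = n_params,
    AIC = -2 * loglik + 2 * n_params,
    AICc = ic_aicc(loglik, n_params, N),
    BIC = -2 * loglik + log(N) * n_params,
    KIC = -2 * loglik + 3 * (n_params + 1))
}

#' Scan the number of clusters
#'
#' Fits the clustering for each value of `k` in `k_range` and tabulates the
#' four goodness-of-fit criteria. A sharp drop of the statistics at some K is
#' the usual indication of the supported number of clusters; the table
#' reports first differences (`d_aic`, ...) but deliberately makes no
#' automatic choice.
#'
#' @param x a [genotype_matrix].
#' @param k_range integers to scan (default `1:6`).
#' @param ... passed on to [hwclust()] (init, tol, alpha, seed, ...).
#' @return A data frame of class `hwclust_scan` with columns `K`, `loglik`,
#'   `n_params`, `converged`, `AIC`, `AICc`, `BIC`, `KIC` and their first
#'   differences; the row index of the minimum of each criterion is attached
#'   as attribute `best`. Fits are attached as attribute `fits`.
#' @export
choose_k <- function(x, k_range = 1:6, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 1L), all(k_range <= n_ind(x)))
  fits <- vector("list", length(k_range))
  rows <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fit <- tryCatch(hwclust(x, k = k_range[i], ...), error = function(e) e)
    fits[[i]] <- fit
    if (inherits(fit, "error")) {
      warning("k = ", k_range[i], " failed: ", conditionMessage(fit))
      rows[[i]] <- data.frame(K = k_range[i], loglik = NA_real_,
                              n_params = NA_integer_, converged = NA,
                              AIC = NA_real_, AICc = NA_real_,
                              BIC = NA_real_, KIC = NA_real_)
      next
    }
    aicc <- withCallingHandlers(
      tryCatch(AICc(fit), error = function(e) {
        warning("k = ", k_range[i], ": ", conditionMessage(e))
        NA_real_
      }),
      warning = function(w) {
        if (grepl("outside its domain", conditionMessage(w))) {
          invokeRestart("muffleWarning") # scan reports raw values for all K
        }
      })
    rows[[i]] <- data.frame(
      K = k_range[i], loglik = fit$loglik, n_params = fit$n_params,
      converged = fit$converged, AIC = AIC(fit), AICc = aicc,
      BIC = BIC(fit), KIC = KIC(fit))
  }
  out <- do.call(rbind, rows)
  for (crit in c("AIC", "AICc", "BIC", "KIC")) {
    out[[paste0("d_", crit)]] <- c(NA, diff(out[[crit]]))
  }
  attr(out, "best") <- vapply(c("AIC", "AICc", "BIC", "KIC"), function(crit) {
    if (all(is.na(out[[crit]]))) NA_integer_
    else out$K[which.min(out[[crit]])]
  }, integer(1L))
  attr(out, "fits") <- fits
  class(out) <- c("hwclust_scan", "data.frame")
  out
}

#' @export
print.hwclust_scan <- function(x, digits = 2, ...) {
  cat("goodness-of-fit scan over K:\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  best <- attr(x, "best")
  cat("criterion minima: ",
      paste(names(best), best, sep = " at K=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.hwclust_scan <- function(x, ...) {
  crits <- c("AIC", "AICc", "BIC", "KIC")
  cols <- grDevices::hcl.colors(4, "Dark 3")
  rng <- range(unlist(x[crits]), na.rm = TRUE)
  graphics::matplot(x$K, as.matrix(x[crits]), type = "b", pch = 19,
                    lty = 1, col = cols, xlab = "number of clusters K",
                    ylab = "criterion value", ylim = rng, ...)
  graphics::legend("topright", legend = crits, col = cols, lty = 1, pch = 19)
  invisible(x)
}
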