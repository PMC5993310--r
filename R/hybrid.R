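#' Define hybrid classes between two parental populations
#'
#' A hybrid class is characterised by its hybridisation coefficient `w`, the
#' proportion of its genome originating from parental population A: F1
#' corresponds to `w = 0.5`, first-generation backcrosses to `w = 0.25` /
#' `0.75`, second-generation backcrosses to `w = 0.125` / `0.875`, and so on.
#' Parental classes A (`w = 1`) and B (`w = 0`) are always included
#' implicitly. With `include_complements = TRUE` (default) every supplied
#' coefficient other than 0.5 also generates its mirror class `1 - w`, so
#' `hybrid_scheme(c(0.5, 0.25, 0.125))` yields the seven classes
#' A, BC2-A, BC1-A, F1, BC1-B, BC2-B, B.
#'
#' @param coefficients hybridisation coefficients, each strictly between 0
#'   and 1.
#' @param include_complements also add `1 - w` for every `w != 0.5`.
#' @return An object of class `hybrid_scheme`: a list with elements `w`
#'   (all class coefficients, parents included, in decreasing order) and
#'   `labels`.
#' @export
hybrid_scheme <- function(coefficients = c(0.5, 0.25, 0.125),
                          include_complements = TRUE) {
  w <- as.numeric(coefficients)
  if (length(w) == 0L || any(!is.finite(w)) || any(w <= 0 | w >= 1)) {
    stop("hybrid coefficients must lie strictly between 0 and 1")
  }
  if (include_complements) w <- c(w, 1 - w)
  w <- sort(unique(round(w / 1e-12) * 1e-12), decreasing = TRUE)
  # deduplicate at tolerance 1e-12
  w <- w[c(TRUE, diff(w) < -1e-12)]
  w_all <- c(1, w, 0)
  structure(list(w = w_all, labels = hybrid_class_labels(w_all)),
            class = "hybrid_scheme")
}

hybrid_class_labels <- function(w) {
  vapply(w, function(wi) {
    if (wi == 1) return("A")
    if (wi == 0) return("B")
    if (abs(wi - 0.5) < 1e-9) return("F1")
    # backcross ladder: BCn-A has w = 1 - 2^-(n+1), BCn-B has w = 2^-(n+1)
    toward_a <- wi > 0.5
    p <- if (toward_a) 1 - wi else wi
    n <- -log2(p) - 1
    if (abs(n - round(n)) < 1e-6 && round(n) >= 1) {
      sprintf("BC%d-%s", round(n), if (toward_a) "A" else "B")
    } else {
      sprintf("H(w=%g)", wi)
    }
  }, character(1L))
}

#' @export
print.hybrid_scheme <- function(x, ...) {
  cat("hybrid_scheme with", length(x$w), "classes:\n")
  print(stats::setNames(x$w, x$labels))
  invisible(x)
}

#' Mixture allele frequencies of a hybrid class
#'
#' The allelic composition of a hybrid population is the convex combination
#' `w * fA + (1 - w) * fB` of the two parental allele-frequency vectors,
#' applied locus by locus.
#'
#' @param fA,fB parental allele frequencies: numeric vectors or matrices over
#'   the same allele universe.
#' @param w hybridisation coefficient in `[0, 1]`.
#' @return An object of the same shape as `fA`.
#' @export
hybrid_frequencies <- function(fA, fB, w) {
  if (length(fA) != length(fB)) {
    stop("parental frequencies have mismatched allele universes")
  }
  stopifnot(is.numeric(w), length(w) == 1L, w >= 0, w <= 1)
  w * fA + (1 - w) * fB
}
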