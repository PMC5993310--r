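#' Pairwise true positive and true negative rates of a clustering
#'
#' Compares an inferred partition to the true one over all unordered pairs
#' of individuals, without requiring cluster labels to match: the true
#' positive rate (TPR) is the proportion of same-population pairs that were
#' clustered together, the true negative rate (TNR) the proportion of
#' different-population pairs placed in different clusters. Their sum is
#' proportional to the Rand index. Both rates are invariant to any
#' relabelling of the predicted clusters. Pair counts are computed exactly
#' from the truth x prediction contingency table.
#'
#' @param truth true population labels (length N >= 2).
#' @param predicted inferred cluster labels (length N).
#' @return A list with `tpr`, `tnr`, `n_pairs_same`, `n_pairs_diff`. A rate
#'   whose denominator is empty (all-same or all-different truth) is `NaN`
#'   with a warning.
#' @export
pairwise_tpr_tnr <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 2L)
  N <- length(truth)
  tab <- table(truth, predicted)
  pairs <- function(n) n * (n - 1) / 2
  same_truth <- sum(pairs(rowSums(tab)))
  same_pred <- sum(pairs(colSums(tab)))
  same_both <- sum(pairs(tab))
  total <- pairs(N)
  diff_truth <- total - same_truth
  diff_both <- total - same_truth - same_pred + same_both
  tpr <- if (same_truth == 0) {
    warning("TPR undefined: no same-population pair in truth")
    NaN
  } else same_both / same_truth
  tnr <- if (diff_truth == 0) {
    warning("TNR undefined: no different-population pair in truth")
    NaN
  } else diff_both / diff_truth
  list(tpr = tpr, tnr = tnr,
       n_pairs_same = same_truth, n_pairs_diff = diff_truth)
}

# Translate the fitted class labels (A, B, F1, BC1-A, ...) into the truth
# vocabulary (P1, P2, F1, BC1-P1, ...), choosing the A<->P1 or A<->P2
# orientation by majority vote among truth-parental individuals.
match_parental_labels <- function(truth, fit) {
  stopifnot(inherits(fit, "hwclust"))
  if (is.null(fit$scheme)) stop("fit has unlabelled clusters; use pairwise_tpr_tnr()")
  pred <- as.character(fit$groups)
  truth <- as.character(truth)
  par_idx <- truth %in% c("P1", "P2")
  votes_a_is_p1 <- sum((truth[par_idx] == "P1" & pred[par_idx] == "A") |
                         (truth[par_idx] == "P2" & pred[par_idx] == "B"))
  votes_a_is_p2 <- sum((truth[par_idx] == "P2" & pred[par_idx] == "A") |
                         (truth[par_idx] == "P1" & pred[par_idx] == "B"))
  tie <- votes_a_is_p1 == votes_a_is_p2
  if (tie) warning("ambiguous parental matching; breaking tie toward A = P1")
  a_is_p1 <- votes_a_is_p1 >= votes_a_is_p2
  fit_labels <- levels(fit$groups)
  mapped <- fit_labels
  mapped <- sub("^A$", if (a_is_p1) "P1" else "P2", mapped)
  mapped <- sub("^B$", if (a_is_p1) "P2" else "P1", mapped)
  mapped <- sub("-A$", if (a_is_p1) "-P1" else "-P2", mapped)
  mapped <- sub("-B$", if (a_is_p1) "-P2" else "-P1", mapped)
  stats::setNames(mapped, fit_labels)
}

#' Per-class correct-assignment rates in hybrid mode
#'
#' Proportion of individuals whose class (parental, F1, BC1, BC2, ...) was
#' correctly identified by a hybrid-mode fit. Parental clusters A/B are
#' matched to the truth's P1/P2 by majority vote among truth-parental
#' individuals (ties broken toward A = P1, with a warning), and hybrid class
#' labels are re-oriented accordingly, so the result is invariant to
#' swapping the parental poles of the fit.
#'
#' @param truth true class labels in the vocabulary `P1`, `P2`, `F1`,
#'   `BC1-P1`, `BC1-P2`, `BC2-P1`, `BC2-P2`, ...
#' @param fit a hybrid-mode [hwclust] fit.
#' @return A list with `per_class` (named proportions, one per truth class),
#'   `overall`, and `mapping` (fit label -> truth label).
#' @export
correct_assignment <- function(truth, fit) {
  mapping <- match_parental_labels(truth, fit)
  pred <- unname(mapping[as.character(fit$groups)])
  truth <- as.character(truth)
  classes <- unique(truth)
  per_class <- vapply(classes, function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1L))
  list(per_class = per_class, overall = mean(pred == truth),
       mapping = mapping)
}

#' Mean support for the true class
#'
#' Mean membership probability a hybrid-mode fit assigns to each
#' individual's true class, per class and overall, after the same parental
#' matching as [correct_assignment()].
#'
#' @inheritParams correct_assignment
#' @return A list with `per_class`, `overall`, `mapping`.
#' @export
mean_support <- function(truth, fit) {
  mapping <- match_parental_labels(truth, fit)
  truth <- as.character(truth)
  inv <- stats::setNames(names(mapping), mapping) # truth label -> fit column
  col_idx <- match(unname(inv[truth]), colnames(fit$memberships))
  if (anyNA(col_idx)) {
    stop("truth contains classes absent from the fitted scheme: ",
         paste(unique(truth[is.na(col_idx)]), collapse = ", "))
  }
  support <- fit$memberships[cbind(seq_along(truth), col_idx)]
  classes <- unique(truth)
  per_class <- vapply(classes, function(cl) mean(support[truth == cl]),
                      numeric(1L))
  list(per_class = per_class, overall = mean(support), mapping = mapping)
}
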