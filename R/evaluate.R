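# Entropy-based agreement between a predicted labeling and a reference.
# All entropies use natural logarithms; the three metrics are ratios and are
# therefore base-invariant.

contingency <- function(reference, prediction) {
  if (length(reference) != length(prediction))
    stop("reference and prediction must label the same cells", call. = FALSE)
  table(reference = as.character(reference),
        prediction = as.character(prediction))
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# H(row | col) from a contingency table
conditional_entropy <- function(tab) {
  n <- sum(tab)
  h <- 0
  for (k in seq_len(ncol(tab))) {
    nk <- sum(tab[, k])
    nz <- tab[, k][tab[, k] > 0]
    h <- h - sum(nz / n * log(nz / nk))
  }
  h
}

#' Homogeneity of a clustering with respect to a reference
#'
#' `1 - H(C|K) / H(C)`: the extent to which each predicted cluster contains
#' cells of only one reference class. Splitting clusters can never decrease
#' it; a prediction putting everything in one cluster over a mixed reference
#' scores 0. When the reference has zero entropy (a single class) the score
#' is 1 by convention.
#'
#' @param reference Reference class labels, one per cell.
#' @param prediction Predicted cluster labels, one per cell.
#' @return A number in `[0, 1]`.
#' @export
homogeneity <- function(reference, prediction) {
  tab <- contingency(reference, prediction)
  hc <- entropy_from_counts(rowSums(tab))
  if (hc == 0) return(1)
  1 - conditional_entropy(tab) / hc
}

#' Completeness of a clustering with respect to a reference
#'
#' `1 - H(K|C) / H(K)`: the extent to which each reference class lands in a
#' single predicted cluster. Merging predicted clusters can never decrease
#' it; the all-one-cluster prediction scores 1 (zero-entropy convention).
#' Completeness is homogeneity with the roles of the two labelings swapped.
#'
#' @inheritParams homogeneity
#' @return A number in `[0, 1]`.
#' @export
completeness <- function(reference, prediction) {
  homogeneity(prediction, reference)
}

#' V-measure: harmonic mean of homogeneity and completeness
#'
#' `2 h c / (h + c)`, or 0 when both are 0. Balances the over-clustering
#' bias of homogeneity against the under-clustering bias of completeness.
#'
#' @inheritParams homogeneity
#' @return A number in `[0, 1]`.
#' @export
v_measure <- function(reference, prediction) {
  h <- homogeneity(reference, prediction)
  c <- completeness(reference, prediction)
  if (h + c == 0) return(0)
  2 * h * c / (h + c)
}

#' All agreement metrics at once
#'
#' @inheritParams homogeneity
#' @return One-row tibble with `homogeneity`, `completeness`, `v_measure`,
#'   `n_clusters_pred`, `n_clusters_ref`.
#' @export
label_agreement <- function(reference, prediction) {
  tibble::tibble(
    homogeneity = homogeneity(reference, prediction),
    completeness = completeness(reference, prediction),
    v_measure = v_measure(reference, prediction),
    n_clusters_pred = dplyr::n_distinct(prediction),
    n_clusters_ref = dplyr::n_distinct(reference)
  )
}
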