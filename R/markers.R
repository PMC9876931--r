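#' Rank cluster markers by combined significance and effect size
#'
#' For every cluster, each feature is tested cluster-vs-rest with a two-sided
#' Welch t-test on the normalized values. Features are ranked twice — by
#' p-value (rank 0 = most significant) and by log-fold-change (rank 0 =
#' largest positive difference of means) — and the two ranks are averaged:
#' `r_combined = (r_pval + r_lfc) / 2`. The top `top_markers` features per
#' cluster (ascending combined rank; ties broken by p-value, then feature id)
#' form the cluster's marker list, and the union over clusters is the
#' discriminative feature set used by the reassignment score.
#'
#' A singleton cluster leaves the t-test undefined; its features all receive
#' the worst possible p-value rank (with a warning) and are ordered by fold
#' change alone.
#'
#' @param fm Normalized [feature_matrix()].
#' @param labels Character vector of cluster labels, one per cell.
#' @param top_markers Markers kept per cluster (capped at the feature count).
#' @return A tibble of class `marker_table` with columns `cluster`, `feature`,
#'   `position` (1-based within the cluster's top list), `p_value`, `lfc`,
#'   `r_pval`, `r_lfc`, `r_combined`. The union of all top lists is stored in
#'   `attr(, "feature_union")`.
#' @export
rank_markers <- function(fm, labels, top_markers = 30L) {
  stopifnot(inherits(fm, "feature_matrix"), length(labels) == n_cells(fm))
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L)
    stop("marker ranking needs at least two clusters", call. = FALSE)
  X <- fm$values
  n <- nrow(X)
  tot <- colSums(X)
  tot2 <- colSums(X^2)
  n_keep <- min(top_markers, ncol(X))

  per_cluster <- purrr::map(clusters, function(cl) {
    idx <- labels == cl
    n1 <- sum(idx); n2 <- n - n1
    s1 <- colSums(X[idx, , drop = FALSE])
    ss1 <- colSums(X[idx, , drop = FALSE]^2)
    m1 <- s1 / n1
    m2 <- (tot - s1) / n2
    lfc <- m1 - m2
    if (n1 < 2L) {
      warning("cluster `", cl, "` is a singleton; p-value ranks set to worst",
              call. = FALSE)
      p <- rep(1, ncol(X))
      r_pval <- rep(ncol(X) - 1, ncol(X))
    } else {
      v1 <- pmax(ss1 - n1 * m1^2, 0) / (n1 - 1)
      v2 <- pmax(tot2 - ss1 - n2 * m2^2, 0) / (n2 - 1)
      se2 <- v1 / n1 + v2 / n2
      t_stat <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf * sign(lfc)))
      df <- ifelse(se2 > 0,
                   se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                   1)
      p <- 2 * stats::pt(-abs(t_stat), df)
      p[!is.finite(t_stat)] <- 0
      p[se2 == 0 & lfc == 0] <- 1
      r_pval <- rank(p, ties.method = "min") - 1
    }
    r_lfc <- rank(-lfc, ties.method = "min") - 1
    r_combined <- (r_pval + r_lfc) / 2
    ord <- order(r_combined, p, fm$feature_ids)[seq_len(n_keep)]
    tibble::tibble(cluster = cl,
                   feature = fm$feature_ids[ord],
                   position = seq_len(n_keep),
                   p_value = unname(p[ord]), lfc = unname(lfc[ord]),
                   r_pval = unname(r_pval[ord]), r_lfc = unname(r_lfc[ord]),
                   r_combined = unname(r_combined[ord]))
  })
  out <- dplyr::bind_rows(per_cluster)
  attr(out, "feature_union") <- unique(out$feature)
  class(out) <- c("marker_table", class(out))
  out
}

#' Union of top markers across clusters
#' @param markers A `marker_table` from [rank_markers()].
#' @return Character vector of feature ids.
#' @export
marker_union <- function(markers) attr(markers, "feature_union")
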