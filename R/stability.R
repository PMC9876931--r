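#' Centroid reassignment score
#'
#' Measures how reliably a cluster's cells fall back onto their own centroid.
#' The matrix is restricted to the union of top markers over all clusters,
#' reduced by PCA (mean-centered, unscaled) to
#' `P = min(n_pcs, |L| - 1, I - 1)` components, and each cluster's centroid is
#' the mean of its member cells in that space. Every cell is then assigned to
#' its Euclidean-nearest centroid, and the score of a cluster is the fraction
#' of its cells that return to it — 1 for a compact well-separated cluster,
#' about 1/k for labels drawn at random over k interchangeable groups.
#'
#' @param fm Normalized [feature_matrix()].
#' @param labels Cluster labels, one per cell.
#' @param markers `marker_table` from [rank_markers()] on the same labels
#'   (computed if `NULL`).
#' @param n_pcs Requested number of principal components.
#' @return Named numeric vector, one score in `[0, 1]` per cluster.
#' @export
reassign_score <- function(fm, labels, markers = NULL, n_pcs = 30L) {
  stopifnot(inherits(fm, "feature_matrix"), length(labels) == n_cells(fm))
  labels <- as.character(labels)
  if (is.null(markers)) markers <- rank_markers(fm, labels)
  space <- marker_pca_space(fm, marker_union(markers), n_pcs)
  nearest <- nearest_centroid(space, labels)
  clusters <- sort(unique(labels))
  vapply(clusters, function(cl) mean(nearest[labels == cl] == cl), numeric(1))
}

# PCA embedding of the marker-restricted matrix; rows follow fm cell order
marker_pca_space <- function(fm, features, n_pcs) {
  features <- intersect(features, fm$feature_ids)
  if (length(features) < 2L)
    stop("marker union has fewer than two features", call. = FALSE)
  Xl <- fm$values[, features, drop = FALSE]
  p <- min(n_pcs, length(features) - 1L, nrow(Xl) - 1L)
  if (p < 1L) stop("cannot extract a principal component from the marker space",
                   call. = FALSE)
  pca <- stats::prcomp(Xl, center = TRUE, scale. = FALSE, rank. = p)
  pca$x[, seq_len(p), drop = FALSE]
}

# label of the Euclidean-nearest centroid for every row of `space`;
# centroids are means of `centroid_labels` groups over `centroid_rows`
nearest_centroid <- function(space, centroid_labels, centroid_rows = NULL,
                             query_rows = NULL) {
  if (is.null(centroid_rows)) centroid_rows <- seq_len(nrow(space))
  if (is.null(query_rows)) query_rows <- seq_len(nrow(space))
  centroid_labels <- as.character(centroid_labels)
  clusters <- sort(unique(centroid_labels))
  cen <- vapply(clusters, function(cl) {
    colMeans(space[centroid_rows[centroid_labels == cl], , drop = FALSE])
  }, numeric(ncol(space)))
  cen <- matrix(cen, ncol = length(clusters),
                dimnames = list(NULL, clusters))       # P x C
  q <- space[query_rows, , drop = FALSE]
  # squared distances via ||q||^2 - 2 q'c + ||c||^2 (||q||^2 constant per row)
  d2 <- -2 * (q %*% cen)
  d2 <- sweep(d2, 2, colSums(cen^2), "+")
  clusters[max.col(-d2, ties.method = "first")]
}

#' Per-feature TF-IDF exclusivity within a cluster
#'
#' Treats expression as binary (value > 0) and scores how exclusive each
#' feature is to a cluster: the term frequency is the fraction of the
#' cluster's cells expressing the feature, the inverse document frequency is
#' `-ln` of the fraction of all cells expressing it, and exclusivity is their
#' product. A pseudo value `eps = 1e-5` guards the logarithm and zero
#' frequencies. A perfect private marker of a cluster covering fraction `q`
#' of the dataset scores `(1 + eps) * (-ln(q + eps))`; a ubiquitous feature
#' scores approximately `-eps`.
#'
#' @param fm Normalized [feature_matrix()].
#' @param labels Cluster labels, one per cell.
#' @param cluster Cluster to score.
#' @param eps Pseudo value added to both frequencies.
#' @return Named numeric vector of exclusivities, one per feature.
#' @export
tfidf_exclusivity <- function(fm, labels, cluster, eps = 1e-5) {
  stopifnot(inherits(fm, "feature_matrix"), length(labels) == n_cells(fm))
  labels <- as.character(labels)
  idx <- labels == as.character(cluster)
  if (!any(idx)) stop("cluster `", cluster, "` has no cells", call. = FALSE)
  expressed <- fm$values > 0
  tf <- colMeans(expressed[idx, , drop = FALSE]) + eps
  idf <- -log(colMeans(expressed) + eps)
  stats::setNames(tf * idf, fm$feature_ids)
}

#' TF-IDF(n) cluster score
#'
#' The exclusivity of a cluster's n-th most exclusive feature (1-based after
#' sorting descending). Low orders (n = 1, 5) reward clusters with even a
#' handful of private markers; n = 10 demands a broader exclusive signature.
#' When fewer than `n` features exist the last one is returned.
#'
#' @param exclusivity Per-feature exclusivities from [tfidf_exclusivity()].
#' @param n Order of the score.
#' @return A single numeric score.
#' @export
tfidf_n_score <- function(exclusivity, n) {
  stopifnot(length(exclusivity) >= 1L, n >= 1L)
  sorted <- sort(exclusivity, decreasing = TRUE)
  sorted[[min(n, length(sorted))]]
}

#' Cross-validated logistic-regression recall per cluster
#'
#' Frames cluster assessment as a multivariate problem: a multinomial
#' logistic regression with L2 regularization is fit on *all* features and
#' evaluated out of sample via stratified k-fold cross-validation, producing
#' a confusion matrix of true versus predicted cluster labels. The default
#' `row_recall` variant scores cluster `c` as `Psi_cc / sum_k Psi_ck` (its
#' recall); the `trace` variant divides by the summed diagonal instead, tying
#' each score to the performance of all clusters jointly.
#'
#' Clusters smaller than the fold count shrink the fold count (minimum 2,
#' with a warning); singleton clusters cannot be cross-validated and score 0.
#'
#' @param fm Normalized [feature_matrix()].
#' @param labels Cluster labels, one per cell.
#' @param n_folds Stratified folds.
#' @param seed Seed for the fold assignment.
#' @param variant `"row_recall"` or `"trace"`.
#' @param lambda Ridge penalty at which the model is evaluated.
#' @return Named numeric vector of scores per cluster, with the pooled
#'   confusion matrix in `attr(, "confusion")`.
#' @export
sccaf_score <- function(fm, labels, n_folds = 5L, seed = 1L,
                        variant = c("row_recall", "trace"), lambda = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), length(labels) == n_cells(fm))
  variant <- match.arg(variant)
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L)
    stop("logistic-regression score needs at least two clusters", call. = FALSE)
  sizes <- table(labels)
  singletons <- names(sizes)[sizes == 1L]
  if (length(singletons))
    warning("singleton clusters scored 0: ", paste(singletons, collapse = ", "),
            call. = FALSE)
  usable <- which(!(labels %in% singletons))
  usable <- usable[order(fm$cell_ids[usable])]  # permutation-invariant folds
  y <- factor(labels[usable], levels = setdiff(clusters, singletons))
  X <- fm$values[usable, , drop = FALSE]
  k <- min(n_folds, min(table(y)))
  if (k < n_folds) {
    k <- max(k, 2L)
    warning("reducing cross-validation folds to ", k,
            " (smallest cluster limits stratification)", call. = FALSE)
  }
  folds <- withr::with_seed(seed, stratified_folds(y, k))
  if (is.null(lambda)) lambda <- 1 / length(y)
  lam_path <- sort(unique(c(10, 1, 0.1, lambda)), decreasing = TRUE)

  confusion <- matrix(0L, nlevels(y), nlevels(y),
                      dimnames = list(levels(y), levels(y)))
  for (f in seq_len(k)) {
    train <- folds != f
    fit <- glmnet::glmnet(X[train, , drop = FALSE], y[train],
                          family = "multinomial", alpha = 0,
                          lambda = lam_path, standardize = FALSE, thresh = 1e-5)
    pred <- predict(fit, X[!train, , drop = FALSE], s = lambda, type = "class")
    pred <- factor(as.character(pred), levels = levels(y))
    confusion <- confusion + unclass(table(y[!train], pred))
  }
  scores <- switch(variant,
    row_recall = ifelse(rowSums(confusion) > 0, diag(confusion) / rowSums(confusion), 0),
    trace = diag(confusion) / sum(diag(confusion))
  )
  out <- stats::setNames(rep(0, length(clusters)), clusters)
  out[names(scores)] <- scores
  attr(out, "confusion") <- confusion
  out
}

# fold id per observation, stratified by class, shuffled within class
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Compute all stability metrics for every annotation set
#'
#' Runs the full per-cluster scoring for each annotation column
#' independently: marker ranking, centroid reassignment, TF-IDF(n) for each
#' configured order, and the cross-validated logistic-regression score. The
#' fold seed is shared across annotation sets so that a duplicated annotation
#' column reproduces identical score rows.
#'
#' @param fm Normalized [feature_matrix()].
#' @param annotations Tibble with a `cell_id` column and one column per
#'   annotation set (see [read_annotations()]), in `fm` cell order.
#' @param config A [run_config()].
#' @return A tibble of class `cluster_stability` with columns `annotation`,
#'   `cluster`, `metric`, `score`, in long format.
#' @export
compute_stability <- function(fm, annotations, config = run_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  annotations <- as_annotation_table(annotations, fm$cell_ids)
  anno_names <- setdiff(colnames(annotations), "cell_id")
  rows <- purrr::map(anno_names, function(a) {
    labels <- annotations[[a]]
    markers <- rank_markers(fm, labels, config$top_markers)
    clusters <- sort(unique(labels))
    reassign <- reassign_score(fm, labels, markers, config$n_pcs_reassign)
    excl <- lapply(stats::setNames(clusters, clusters),
                   function(cl) tfidf_exclusivity(fm, labels, cl))
    tfidf <- lapply(config$tfidf_orders, function(n)
      vapply(excl, tfidf_n_score, numeric(1), n = n))
    names(tfidf) <- paste0("tfidf", config$tfidf_orders)
    sccaf <- sccaf_score(fm, labels, n_folds = config$n_folds,
                         seed = config$random_seed,
                         variant = config$sccaf_variant)
    metrics <- c(list(reassign = reassign), tfidf, list(sccaf = sccaf))
    dplyr::bind_rows(purrr::imap(metrics, function(v, m)
      tibble::tibble(annotation = a, cluster = clusters, metric = m,
                     score = unname(v[clusters]))))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cluster_stability", class(out))
  out
}
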