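#' Triangulate conflicting cluster annotations
#'
#' The full decision-level integration pipeline. Every cluster of every
#' annotation set is scored with the configured stability metrics
#' ([compute_stability()]); each cell's score profile `D` (annotation sets x
#' metrics) then feeds a coalitional game in which the cell is assigned to
#' the annotation with the highest exact Shapley value
#' ([shapley_values()]; beyond `shapley_max_players` sets, rank importance).
#' Winner clusters that keep less than `win_fraction_cutoff` of their
#' originating cluster or fewer than `abs_thresh` cells are pruned and their
#' cells reclassified to the nearest stable centroid in marker-PCA space.
#'
#' @param annotations Data frame with a `cell_id` column and one column per
#'   annotation set; any row order covering the matrix's cells.
#' @param fm Normalized [feature_matrix()] of the same cells.
#' @param config A [run_config()].
#' @param stability Optional precomputed [compute_stability()] table (e.g. to
#'   re-triangulate a different metric subset without re-scoring).
#' @param metrics Optional character vector restricting which metrics of
#'   `stability` enter the game (default: all present).
#' @return An object of class `triangulation` with elements:
#'   * `cells`: per-cell tibble (`cell_id`, `winner_annotation`, `raw_label`,
#'     `final_label`, `pruned` flag, one `phi_<set>` column per annotation set);
#'   * `clusters`: per raw winner cluster (`raw_label`, `size`, `origin_size`,
#'     `wf`, `stable`, `quality`);
#'   * `stability`: the long score table used;
#'   * `config`, `annotation_names`, `importance_method`.
#' @examples
#' \donttest{
#' fx <- make_fixture("experiment1", seed = 7, n_genes = 400)
#' fm <- normalize_cptt(fx$matrix)
#' res <- triangulate(fx$annotations, fm, run_config(random_seed = 7))
#' glance(res)
#' }
#' @export
triangulate <- function(annotations, fm, config = run_config(),
                        stability = NULL, metrics = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "run_config"))
  if (fm$is_raw_counts)
    stop("normalize the matrix first (normalize_cptt()/normalize_clr())",
         call. = FALSE)
  annotations <- as_annotation_table(annotations, fm$cell_ids)
  anno_names <- setdiff(colnames(annotations), "cell_id")
  if (is.null(stability)) stability <- compute_stability(fm, annotations, config)
  if (is.null(metrics)) metrics <- unique(stability$metric)
  stability_used <- dplyr::filter(stability, .data$metric %in% metrics)
  if (!nrow(stability_used)) stop("no stability scores left after metric filter",
                                  call. = FALSE)

  method <- config$importance_method
  if (method == "shapley" && length(anno_names) > config$shapley_max_players) {
    message("more than ", config$shapley_max_players,
            " annotation sets: switching to rank importance")
    method <- "rank"
  }

  phi <- cell_importance(stability_used, annotations, anno_names, metrics,
                         config, method)
  winners <- assign_winners(phi, annotations)
  wf <- winning_fraction(winners$raw_label, annotations)
  wf <- prune_clusters(wf, config)
  stable_set <- wf$raw_label[wf$stable]
  final <- reclassify_cells(fm, winners$raw_label, stable_set, config)

  phi_winner <- phi[cbind(seq_len(nrow(phi)),
                          match(winners$winner_annotation, anno_names))]
  quality <- cluster_quality(phi_winner, winners$raw_label, length(anno_names))

  phi_tbl <- tibble::as_tibble(phi, .name_repair = "minimal")
  colnames(phi_tbl) <- paste0("phi_", anno_names)
  cells <- dplyr::bind_cols(winners, tibble::tibble(final_label = final), phi_tbl) |>
    dplyr::mutate(pruned = .data$raw_label != .data$final_label,
                  .after = "final_label")
  clusters <- dplyr::left_join(wf, quality, by = "raw_label") |>
    dplyr::arrange(dplyr::desc(.data$size))

  structure(
    list(cells = cells, clusters = clusters, stability = stability,
         config = config, annotation_names = anno_names,
         importance_method = method, metrics = metrics),
    class = "triangulation"
  )
}

# per-cell importance matrix (cells x annotation sets); cells sharing the same
# label vector share D, so the game is solved once per unique combination
cell_importance <- function(stability, annotations, anno_names, metrics,
                            config, method) {
  lookup <- list()
  for (a in anno_names) {
    sub <- stability[stability$annotation == a, , drop = FALSE]
    lookup[[a]] <- lapply(stats::setNames(metrics, metrics), function(m) {
      s <- sub[sub$metric == m, , drop = FALSE]
      stats::setNames(s$score, s$cluster)
    })
  }
  key <- do.call(paste, c(lapply(anno_names, function(a) annotations[[a]]),
                          list(sep = "\r")))
  combo_idx <- match(key, unique(key))
  combos <- which(!duplicated(key))
  phi_unique <- matrix(NA_real_, length(combos), length(anno_names))
  for (j in seq_along(combos)) {
    i <- combos[j]
    D <- matrix(NA_real_, length(anno_names), length(metrics),
                dimnames = list(anno_names, metrics))
    for (a in anno_names) {
      cl <- annotations[[a]][i]
      for (m in metrics) D[a, m] <- lookup[[a]][[m]][[cl]]
    }
    phi_unique[j, ] <- switch(method,
      shapley = shapley_values(D, offset = config$offset,
                               adjustment = config$rank_adjustment),
      rank = rank_importance(D, adjustment = config$rank_adjustment,
                             offset = config$offset)
    )
  }
  phi <- phi_unique[combo_idx, , drop = FALSE]
  colnames(phi) <- anno_names
  phi
}

#' @export
print.triangulation <- function(x, ...) {
  cat("<triangulation> ", nrow(x$cells), " cells, ",
      length(x$annotation_names), " annotation sets (",
      paste(x$annotation_names, collapse = ", "), ")\n", sep = "")
  cat("  importance: ", x$importance_method, " | metrics: ",
      paste(x$metrics, collapse = ", "), "\n", sep = "")
  cat("  raw winner clusters: ", nrow(x$clusters),
      " -> final clusters: ", dplyr::n_distinct(x$cells$final_label),
      " (", sum(!x$clusters$stable), " pruned)\n", sep = "")
  invisible(x)
}

#' Tidy per-cell triangulation results
#'
#' @param x A `triangulation` object.
#' @param ... Unused.
#' @return The per-cell tibble (`cell_id`, winner, raw/final labels, pruned
#'   flag, per-annotation importances).
#' @method tidy triangulation
#' @export
tidy.triangulation <- function(x, ...) x$cells

#' One-row summary of a triangulation
#'
#' @param x A `triangulation` object.
#' @param ... Unused.
#' @return Tibble with cell/annotation counts, raw and final cluster counts,
#'   pruned-cell count and mean cluster quality.
#' @method glance triangulation
#' @export
glance.triangulation <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_annotations = length(x$annotation_names),
    n_raw_clusters = nrow(x$clusters),
    n_final_clusters = dplyr::n_distinct(x$cells$final_label),
    n_pruned_cells = sum(x$cells$pruned),
    mean_quality = mean(x$clusters$quality),
    importance_method = x$importance_method
  )
}

#' Plot final cluster composition
#'
#' Bar chart of final cluster sizes, filled by the annotation set each
#' cluster was drawn from.
#'
#' @param object A `triangulation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triangulation
#' @export
autoplot.triangulation <- function(object, ...) {
  df <- object$cells |>
    dplyr::count(.data$final_label, name = "cells") |>
    dplyr::mutate(annotation = split_raw_label(.data$final_label)$annotation)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$final_label, -.data$cells),
                                   y = .data$cells, fill = .data$annotation)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "final cluster", y = "cells", fill = "won by") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of per-cluster stability scores
#'
#' @param stability A `cluster_stability` table from [compute_stability()]
#'   (or the `stability` element of a `triangulation`).
#' @return A ggplot object: metric x cluster tiles, faceted by annotation set.
#' @export
plot_stability <- function(stability) {
  ggplot2::ggplot(stability,
                  ggplot2::aes(x = .data$metric, y = .data$cluster,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~annotation, scales = "free_y") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of modality contributions
#'
#' @param contrib Output of [modality_contribution()].
#' @return A ggplot object.
#' @export
plot_contribution <- function(contrib) {
  ggplot2::ggplot(contrib,
                  ggplot2::aes(x = .data$cluster, y = .data$contribution,
                               fill = .data$modality)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "rank-weighted contribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
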