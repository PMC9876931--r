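#' Winning fraction of raw winner clusters
#'
#' For each raw winner cluster `"<annotation>@<label>"`, the fraction of its
#' originating cluster's cells that actually won with it:
#' `wf_c = |A_c_raw| / |A_c_ori|`. A cluster that convinces only a small
#' minority of its original cells likely won those by chance, so `wf` acts
#' as a per-cluster confidence. Clusters carrying the same label string in
#' two annotation sets are kept distinct by the annotation prefix.
#'
#' @param raw_labels Character vector of raw winner labels per cell
#'   (`"<annotation>@<label>"`, from [assign_winners()]).
#' @param annotations Annotation tibble in the same cell order.
#' @return Tibble with columns `raw_label`, `size` (cells won), `origin_size`
#'   and `wf`.
#' @export
winning_fraction <- function(raw_labels, annotations) {
  won <- tibble::tibble(raw_label = raw_labels) |>
    dplyr::count(.data$raw_label, name = "size")
  parts <- split_raw_label(won$raw_label)
  won$origin_size <- purrr::map2_int(parts$annotation, parts$label, function(a, l) {
    if (!a %in% colnames(annotations))
      stop("raw label refers to unknown annotation set `", a, "`", call. = FALSE)
    sum(annotations[[a]] == l)
  })
  dplyr::mutate(won, wf = .data$size / .data$origin_size)
}

split_raw_label <- function(raw_label) {
  pos <- regexpr("@", raw_label, fixed = TRUE)
  list(annotation = substr(raw_label, 1L, pos - 1L),
       label = substr(raw_label, pos + 1L, nchar(raw_label)))
}

#' Flag unstable winner clusters
#'
#' A winner cluster is unstable when its winning fraction falls below
#' `win_fraction_cutoff` *or* it retains fewer than `abs_thresh` cells
#' (stability estimates on tiny populations are dominated by outliers).
#' Cells of unstable clusters are subsequently reclassified by
#' [reclassify_cells()].
#'
#' @param wf Tibble from [winning_fraction()].
#' @param config A [run_config()] supplying `win_fraction_cutoff` and
#'   `abs_thresh`.
#' @return `wf` with a logical `stable` column.
#' @export
prune_clusters <- function(wf, config = run_config()) {
  out <- dplyr::mutate(wf, stable = .data$wf >= config$win_fraction_cutoff &
                             .data$size >= config$abs_thresh)
  if (!any(out$stable))
    stop("every winner cluster is unstable; lower `win_fraction_cutoff` or ",
         "`abs_thresh`", call. = FALSE)
  out
}

#' Reclassify cells of pruned clusters to the nearest stable centroid
#'
#' Rebuilds the marker-PCA space from the stable winner clusters (markers
#' ranked on the stable cells with the same procedure as the reassignment
#' score) and hands each cell of a pruned cluster the label of the
#' Euclidean-nearest stable-cluster centroid. Stable cells keep their raw
#' labels.
#'
#' @param fm Normalized [feature_matrix()].
#' @param raw_labels Raw winner labels per cell.
#' @param stable_set Character vector of stable raw labels.
#' @param config A [run_config()].
#' @return Character vector of final labels, one per cell.
#' @export
reclassify_cells <- function(fm, raw_labels, stable_set, config = run_config()) {
  stopifnot(length(stable_set) >= 1L)
  final <- raw_labels
  unstable <- !(raw_labels %in% stable_set)
  if (!any(unstable)) return(final)
  stable_idx <- which(!unstable)
  if (length(unique(raw_labels[stable_idx])) >= 2L) {
    sub <- feature_matrix(fm$values[stable_idx, , drop = FALSE],
                          cell_ids = fm$cell_ids[stable_idx],
                          feature_ids = fm$feature_ids,
                          modality = fm$modality, is_raw_counts = FALSE)
    markers <- rank_markers(sub, raw_labels[stable_idx], config$top_markers)
    space <- marker_pca_space(fm, marker_union(markers), config$n_pcs_reassign)
  } else {
    # a single stable cluster: any space works, every cell lands in it
    space <- fm$values[, seq_len(min(2L, ncol(fm$values))), drop = FALSE]
  }
  final[unstable] <- nearest_centroid(space,
                                      centroid_labels = raw_labels[stable_idx],
                                      centroid_rows = stable_idx,
                                      query_rows = which(unstable))
  final
}
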