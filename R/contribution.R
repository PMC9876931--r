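#' Modality contribution to each final cluster
#'
#' Quantifies which modality's features define a cluster: the cluster's
#' top-20 markers (combined p-value/fold-change rank, as in
#' [rank_markers()]) are weighted by list position — the top-1 marker weighs
#' 20, the 20th weighs 1 — and the weights are summed per modality. With at
#' least 20 features the contributions of all modalities therefore sum to
#' 210 for every cluster; with fewer features all of them are used and the
#' position weights `21 - k` are unchanged (the total then being
#' `sum_{k=1..F} (21 - k)`).
#'
#' @param fm Concatenated, normalized [feature_matrix()] with modality tags.
#' @param labels Final cluster labels, one per cell.
#' @param top_n Length of the weighted marker list.
#' @return Tibble with columns `cluster`, `modality`, `contribution`, covering
#'   every (cluster, modality) pair present in the matrix. The underlying
#'   marker lists with positions and weights are in `attr(, "markers")`.
#' @export
modality_contribution <- function(fm, labels, top_n = 20L) {
  stopifnot(inherits(fm, "feature_matrix"), length(labels) == n_cells(fm))
  n_list <- min(top_n, n_features(fm))
  markers <- rank_markers(fm, labels, top_markers = n_list)
  mod_of <- stats::setNames(fm$modality, fm$feature_ids)
  marked <- markers |>
    dplyr::mutate(modality = unname(mod_of[.data$feature]),
                  weight = top_n + 1L - .data$position)
  out <- marked |>
    dplyr::summarise(contribution = sum(.data$weight),
                     .by = c("cluster", "modality")) |>
    tidyr::complete(cluster = sort(unique(labels)),
                    modality = sort(unique(fm$modality)),
                    fill = list(contribution = 0L)) |>
    dplyr::arrange(.data$cluster, .data$modality)
  attr(out, "markers") <- marked
  out
}
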