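#' Log counts-per-ten-thousand normalization
#'
#' Scales each cell's counts to a common depth of 10,000 and applies
#' `log1p`: `x_if = ln(1 + 10000 * c_if / sum_f(c_if))`. This is the standard
#' normalization for RNA and ATAC peak counts; it is invariant to per-cell
#' sequencing depth and monotone in the counts within a cell.
#'
#' @param fm A raw-count [feature_matrix()] (`is_raw_counts = TRUE`) in which
#'   every cell has a positive total count.
#' @return The normalized `feature_matrix` (`is_raw_counts = FALSE`).
#' @export
normalize_cptt <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!fm$is_raw_counts)
    stop("matrix is already normalized (`is_raw_counts` is FALSE)", call. = FALSE)
  totals <- rowSums(fm$values)
  if (any(totals <= 0))
    stop("cells with zero total count: ",
         paste(utils::head(fm$cell_ids[totals <= 0], 5), collapse = ", "),
         call. = FALSE)
  fm$values <- log1p(fm$values / totals * 1e4)
  fm$is_raw_counts <- FALSE
  fm
}

#' Centered log-ratio normalization for antibody-derived tags
#'
#' Within each cell, `y_f = ln(x_f + 1) - mean_f ln(x_f + 1)`: the log of each
#' tag's pseudocounted abundance relative to the cell's geometric mean. Rows
#' of the result sum to zero, and multiplying all of a cell's counts by a
#' constant shifts nothing, which removes cell-wise staining/capture depth —
#' the standard treatment of ADT counts in CITE-seq.
#'
#' @param fm A raw-count [feature_matrix()] with non-negative values.
#' @return The normalized `feature_matrix` (`is_raw_counts = FALSE`).
#' @export
normalize_clr <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!fm$is_raw_counts)
    stop("matrix is already normalized (`is_raw_counts` is FALSE)", call. = FALSE)
  lg <- log1p(fm$values)
  fm$values <- lg - rowMeans(lg)
  fm$is_raw_counts <- FALSE
  fm
}

#' Concatenate normalized modalities into one feature matrix
#'
#' Stacks the feature columns of several normalized blocks measured on the
#' same cells into a single matrix so that all molecular features are judged
#' jointly downstream. Blocks may list their (identical) cell sets in any
#' order; all are reordered to the first block's order. Modality tags and
#' the prefixed feature ids are preserved.
#'
#' @param ... Normalized [feature_matrix()] objects (or a single list of them).
#' @return One `feature_matrix` with `sum(F_b)` features.
#' @export
concat_modalities <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1]], "feature_matrix"))
    blocks <- blocks[[1]]
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, logical(1), "feature_matrix")))
  if (any(vapply(blocks, function(b) b$is_raw_counts, logical(1))))
    stop("all blocks must be normalized before concatenation", call. = FALSE)
  ref <- blocks[[1]]$cell_ids
  for (b in blocks[-1]) {
    if (!setequal(b$cell_ids, ref))
      stop("blocks do not share the same cell set", call. = FALSE)
  }
  blocks <- lapply(blocks, reorder_cells, cell_ids = ref)
  feature_matrix(
    do.call(cbind, lapply(blocks, `[[`, "values")),
    cell_ids = ref,
    feature_ids = unlist(lapply(blocks, `[[`, "feature_ids"), use.names = FALSE),
    modality = unlist(lapply(blocks, `[[`, "modality"), use.names = FALSE),
    is_raw_counts = FALSE
  )
}
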