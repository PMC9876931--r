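#' Construct a cell-by-feature matrix with modality tags
#'
#' The central container of the package: a dense numeric matrix of cells
#' (rows) by features (columns), each feature tagged with the modality it was
#' measured in (`"RNA"`, `"ADT"`, `"ATAC"`, or a custom `"OTHER:<tag>"`).
#' Feature ids are prefixed with `"<modality>:"` so that features remain
#' globally unique after multimodal concatenation.
#'
#' @param values Numeric matrix, cells x features. Row/column names, if
#'   present, are overridden by `cell_ids` / `feature_ids`.
#' @param cell_ids Character vector of unique cell identifiers (length =
#'   `nrow(values)`).
#' @param feature_ids Character vector of feature identifiers (length =
#'   `ncol(values)`); prefixed with the modality tag unless already prefixed.
#' @param modality Single modality tag applied to all features, or a character
#'   vector with one tag per feature.
#' @param is_raw_counts Logical; `TRUE` when `values` holds raw (non-negative)
#'   counts that still need normalization.
#'
#' @return An object of class `feature_matrix`: a list with elements `values`,
#'   `cell_ids`, `feature_ids`, `modality` and `is_raw_counts`.
#' @examples
#' fm <- feature_matrix(matrix(rpois(20, 5), 4, 5),
#'                      cell_ids = paste0("cell", 1:4),
#'                      feature_ids = paste0("g", 1:5),
#'                      modality = "RNA")
#' fm
#' @export
feature_matrix <- function(values, cell_ids = rownames(values),
                           feature_ids = colnames(values),
                           modality = "RNA", is_raw_counts = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values))
    stop("`cell_ids` length (", length(cell_ids), ") does not match number of rows (",
         nrow(values), ")", call. = FALSE)
  if (length(feature_ids) != ncol(values))
    stop("`feature_ids` length (", length(feature_ids),
         ") does not match number of columns (", ncol(values), ")", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a feature_matrix needs at least one cell and one feature", call. = FALSE)
  modality <- as.character(modality)
  if (length(modality) == 1L) modality <- rep(modality, ncol(values))
  if (length(modality) != ncol(values))
    stop("`modality` must be length 1 or one tag per feature", call. = FALSE)

  # prefix feature ids with their modality so concatenated matrices stay unique
  unprefixed <- !startsWith(feature_ids, paste0(modality, ":"))
  feature_ids[unprefixed] <- paste0(modality[unprefixed], ":", feature_ids[unprefixed])

  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 3),
                                       collapse = ", "), call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids after modality prefixing: ",
         paste(utils::head(unique(feature_ids[duplicated(feature_ids)]), 3),
               collapse = ", "), call. = FALSE)
  if (is_raw_counts && any(values < 0))
    stop("raw count matrix contains negative values", call. = FALSE)

  dimnames(values) <- list(cell_ids, feature_ids)
  structure(
    list(values = values, cell_ids = cell_ids, feature_ids = feature_ids,
         modality = modality, is_raw_counts = is_raw_counts),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(x$modality)
  cat("<feature_matrix> ", length(x$cell_ids), " cells x ", length(x$feature_ids),
      " features (", if (x$is_raw_counts) "raw counts" else "normalized", ")\n",
      sep = "")
  cat("  modalities: ", paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Number of cells / features in a feature matrix
#' @param x A [feature_matrix()].
#' @return Integer count.
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname n_cells
#' @export
n_features <- function(x) ncol(x$values)

# reorder cells to a reference id vector (order-normalization)
reorder_cells <- function(x, cell_ids) {
  idx <- match(cell_ids, x$cell_ids)
  if (anyNA(idx))
    stop("cells missing from feature matrix: ",
         paste(utils::head(cell_ids[is.na(idx)], 3), collapse = ", "), call. = FALSE)
  x$values <- x$values[idx, , drop = FALSE]
  x$cell_ids <- x$cell_ids[idx]
  x
}
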