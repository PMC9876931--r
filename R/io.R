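#' Read a cell-by-feature matrix from disk
#'
#' Reads either a Matrix Market triplet (`.mtx` plus `features.tsv` /
#' `barcodes.tsv` sidecars) or a dense delimited file with a header row and
#' cell ids in the first column. MTX files written in either orientation
#' (cells x features or features x cells) are accepted; the orientation is
#' detected from the lengths of the two id files and the matrix is returned
#' as cells x features either way.
#'
#' @param path Path to the `.mtx` or dense `.csv`/`.tsv` file.
#' @param format `"mtx"` or `"csv"` (dense; the delimiter is sniffed from the
#'   file extension, tab for `.tsv`).
#' @param modality Modality tag applied to every feature (see
#'   [feature_matrix()]).
#' @param features,barcodes For `format = "mtx"`: paths to the feature and
#'   barcode id files (defaults: `features.tsv` and `barcodes.tsv` next to
#'   the matrix). First column is used.
#' @param is_raw_counts Logical, passed through to [feature_matrix()].
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, format = c("mtx", "csv"), modality = "RNA",
                                features = NULL, barcodes = NULL,
                                is_raw_counts = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(features)) features <- file.path(dir, "features.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    for (f in c(features, barcodes))
      if (!file.exists(f)) stop("sidecar file not found: ", f, call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    feat_ids <- read_id_column(features)
    cell_ids <- read_id_column(barcodes)
    if (nrow(m) == length(cell_ids) && ncol(m) == length(feat_ids)) {
      # cells x features on disk
    } else if (nrow(m) == length(feat_ids) && ncol(m) == length(cell_ids)) {
      m <- t(m)
    } else {
      stop("matrix dimensions ", nrow(m), " x ", ncol(m),
           " match neither orientation of ", length(cell_ids), " barcodes x ",
           length(feat_ids), " features", call. = FALSE)
    }
    feature_matrix(m, cell_ids = cell_ids, feature_ids = feat_ids,
                   modality = modality, is_raw_counts = is_raw_counts)
  } else {
    delim <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
    tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
    if (ncol(tbl) < 2L) stop("dense matrix file needs an id column plus features",
                             call. = FALSE)
    m <- as.matrix(tbl[, -1, drop = FALSE])
    feature_matrix(m, cell_ids = tbl[[1]], feature_ids = colnames(tbl)[-1],
                   modality = modality, is_raw_counts = is_raw_counts)
  }
}

read_id_column <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  as.character(tbl[[1]])
}

#' Read conflicting annotation sets for a set of cells
#'
#' Reads a delimited table with one row per cell and one column per annotation
#' set, reorders rows to match `cell_ids`, and validates completeness: every
#' cell must appear exactly once and carry a non-missing label in every set.
#'
#' @param path TSV/CSV file with a cell-id column (default: first column, or
#'   the column named in `id_col`) and one column per annotation set.
#' @param cell_ids Character vector of cell ids the table must cover (usually
#'   `fm$cell_ids`); rows are reordered to this order.
#' @param id_col Name of the cell-id column; defaults to the first column.
#' @return A tibble with column `cell_id` followed by one character column per
#'   annotation set, rows in `cell_ids` order.
#' @export
read_annotations <- function(path, cell_ids, id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (is.null(id_col)) id_col <- colnames(tbl)[1]
  if (!id_col %in% colnames(tbl))
    stop("no cell-id column `", id_col, "` in ", path, call. = FALSE)
  tbl <- dplyr::rename(tbl, cell_id = dplyr::all_of(id_col))
  tbl$cell_id <- as.character(tbl$cell_id)
  as_annotation_table(tbl, cell_ids)
}

#' Validate and order-normalize an annotation table
#'
#' @param tbl Data frame with a `cell_id` column and one column per annotation
#'   set (converted to character).
#' @param cell_ids Reference cell order.
#' @return Tibble in `cell_ids` order.
#' @export
as_annotation_table <- function(tbl, cell_ids) {
  tbl <- tibble::as_tibble(tbl)
  if (!"cell_id" %in% colnames(tbl)) stop("annotation table needs a `cell_id` column",
                                          call. = FALSE)
  if (ncol(tbl) < 2L) stop("annotation table has no annotation columns", call. = FALSE)
  idx <- match(cell_ids, tbl$cell_id)
  if (anyNA(idx))
    stop("cells missing from annotation table: ",
         paste(utils::head(cell_ids[is.na(idx)], 3), collapse = ", "), call. = FALSE)
  tbl <- tbl[idx, , drop = FALSE]
  anno_cols <- setdiff(colnames(tbl), "cell_id")
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::all_of(anno_cols), as.character))
  for (a in anno_cols) {
    if (anyNA(tbl[[a]]) || any(tbl[[a]] == ""))
      stop("annotation set `", a, "` has missing labels", call. = FALSE)
  }
  tbl
}

#' Run configuration for annotation triangulation
#'
#' Bundles every tunable of the pipeline with its default. Defaults follow the
#' method's standard settings: rank-tolerance offset 0.01, winning-fraction
#' cutoff 0.25, minimum retained cluster size 10, 30 markers per cluster,
#' TF-IDF order 10 (optionally adding 5), winner-take-all rank adjustment, and
#' exact Shapley importance with an automatic switch to pure ranking beyond 15
#' annotation sets.
#'
#' @param offset Additive rank tolerance: scores within `offset` of the leader
#'   share the top rank. Stability scores live on a 0-2 scale, so the default
#'   0.01 is a ~1% slack.
#' @param win_fraction_cutoff Winner clusters retaining less than this
#'   fraction of their originating cluster are pruned.
#' @param abs_thresh Winner clusters with fewer cells than this are pruned.
#' @param top_markers Markers ranked per cluster for the reassignment score
#'   and modality contributions.
#' @param tfidf_orders Integer vector of TF-IDF orders to score (e.g. `c(10, 5)`).
#' @param n_pcs_reassign Principal components for the marker-space
#'   reassignment score (capped at the available rank).
#' @param rank_adjustment `"all_or_none"` (winner takes all; default) or
#'   `"classic"` (every player keeps its offset-adjusted rank).
#' @param importance_method `"shapley"` (exact enumeration) or `"rank"`.
#'   Automatically falls back to `"rank"` when more than `shapley_max_players`
#'   annotation sets are supplied.
#' @param shapley_max_players Player count above which exact Shapley is
#'   replaced by rank importance.
#' @param sccaf_variant `"row_recall"` (per-cluster recall, default) or
#'   `"trace"` (diagonal share of the confusion matrix).
#' @param n_folds Cross-validation folds for the logistic-regression score.
#' @param random_seed Seed for every stochastic step (cross-validation fold
#'   assignment).
#' @return A list of class `run_config`.
#' @export
run_config <- function(offset = 0.01,
                       win_fraction_cutoff = 0.25,
                       abs_thresh = 10L,
                       top_markers = 30L,
                       tfidf_orders = 10L,
                       n_pcs_reassign = 30L,
                       rank_adjustment = c("all_or_none", "classic"),
                       importance_method = c("shapley", "rank"),
                       shapley_max_players = 15L,
                       sccaf_variant = c("row_recall", "trace"),
                       n_folds = 5L,
                       random_seed = 1L) {
  stopifnot(offset >= 0, win_fraction_cutoff >= 0, win_fraction_cutoff <= 1,
            abs_thresh >= 0, top_markers >= 1, all(tfidf_orders >= 1),
            n_pcs_reassign >= 1, n_folds >= 2)
  structure(
    list(offset = offset,
         win_fraction_cutoff = win_fraction_cutoff,
         abs_thresh = as.integer(abs_thresh),
         top_markers = as.integer(top_markers),
         tfidf_orders = as.integer(tfidf_orders),
         n_pcs_reassign = as.integer(n_pcs_reassign),
         rank_adjustment = match.arg(rank_adjustment),
         importance_method = match.arg(importance_method),
         shapley_max_players = as.integer(shapley_max_players),
         sccaf_variant = match.arg(sccaf_variant),
         n_folds = as.integer(n_folds),
         random_seed = as.integer(random_seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, vals)
}

#' Write triangulation results to a directory
#'
#' Emits three plain-text artifacts: `cells.tsv` (per-cell winner annotation,
#' raw and final labels, and the per-annotation Shapley/importance values),
#' `clusters.tsv` (per raw winner cluster: size, winning fraction, stability
#' flag, quality), and `manifest.json` (configuration, seed, package version).
#'
#' @param result A `triangulation` object from [triangulate()].
#' @param outdir Output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "triangulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir,
                                call. = FALSE)
  readr::write_tsv(result$cells, file.path(outdir, "cells.tsv"))
  readr::write_tsv(result$clusters, file.path(outdir, "clusters.tsv"))
  manifest <- list(
    package = "triangulatr",
    version = as.character(utils::packageVersion("triangulatr")),
    r_version = as.character(getRversion()),
    config = unclass(result$config),
    annotation_names = result$annotation_names,
    n_cells = nrow(result$cells),
    n_final_clusters = dplyr::n_distinct(result$cells$final_label)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Reload per-cell triangulation labels written by [write_results()]
#'
#' @param outdir Directory previously passed to [write_results()].
#' @return Tibble with the per-cell results.
#' @export
read_results <- function(outdir) {
  readr::read_tsv(file.path(outdir, "cells.tsv"), show_col_types = FALSE,
                  progress = FALSE)
}
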