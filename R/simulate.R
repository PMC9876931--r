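#' Parameters for the group-structured count simulator
#'
#' The generative model mirrors the standard negative-binomial single-cell
#' simulator: gene base means drawn from a gamma distribution, per-group
#' differential-expression (DE) factors drawn log-normally and randomly
#' inverted, log-normal library sizes, and gamma-Poisson (negative binomial)
#' counts with a common biological coefficient of variation. Defaults for
#' the nuisance parameters follow that simulator's published defaults; the
#' group structure (`group_prob`, `de_prob`) is the experiment-specific part.
#'
#' @param batch_cells Number of cells.
#' @param n_genes Number of genes.
#' @param group_prob Probability of each group (sums to 1); its length sets
#'   the number of groups.
#' @param de_prob Per-group probability that a gene is DE in that group.
#' @param de_fac_loc,de_fac_scale Location/scale of the log-normal DE factor.
#' @param lib_loc,lib_scale Location/scale of the log-normal library size.
#' @param mean_shape,mean_rate Gamma parameters of the gene base means.
#' @param bcv_common Common biological coefficient of variation.
#' @param bcv_df Degrees of freedom of the per-gene inverse-chi-square
#'   scaling of the BCV trend.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(batch_cells = 3000L, n_genes = 2000L,
                       group_prob = c(0.23, 0.15, 0.15, 0.23, 0.24),
                       de_prob = c(0.15, 0.15, 0.15, 0.2, 0.4),
                       de_fac_loc = 0.1, de_fac_scale = 0.4,
                       lib_loc = 11, lib_scale = 0.2,
                       mean_shape = 0.6, mean_rate = 0.3,
                       bcv_common = 0.1, bcv_df = 60) {
  if (abs(sum(group_prob) - 1) > 1e-8)
    stop("`group_prob` must sum to 1", call. = FALSE)
  if (length(de_prob) != length(group_prob))
    stop("`de_prob` needs one entry per group", call. = FALSE)
  if (any(de_prob < 0 | de_prob > 1) || any(group_prob < 0))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a group-structured raw count matrix
#'
#' Draws a cells x genes raw count matrix with known group labels. Gene `f`
#' has base mean `lambda_f ~ Gamma(mean_shape, mean_rate)`; in group `g` it
#' is DE with probability `de_prob[g]`, in which case its mean is multiplied
#' by a factor `exp(N(de_fac_loc, de_fac_scale))`, inverted with probability
#' 1/2 so that up- and down-regulation are equally likely. Each cell draws a
#' group from `group_prob` and a library size
#' `~ LogNormal(lib_loc, lib_scale)`; its expected counts are the library
#' size times the group's normalized mean profile. Observed counts are
#' gamma-Poisson (negative binomial) with a mean-dependent biological
#' coefficient of variation, `bcv = (bcv_common + 1 / sqrt(mu)) *
#' sqrt(bcv_df / chi2_f)` with one chi-square draw per gene — lowly expressed
#' genes are proportionally noisier and drop out more often, as in real
#' droplet data.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed; the full draw is reproducible from it.
#' @return A list with `matrix` (raw-count [feature_matrix()]), and `truth`:
#'   a list with `group` (per-cell label `c1..cG`), `de_genes` (genes x
#'   groups logical), `de_factor` (genes x groups multiplicative factors)
#'   and `params`.
#' @export
simulate_counts <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(seed, {
    G <- length(params$group_prob)
    nf <- params$n_genes
    base_mean <- stats::rgamma(nf, shape = params$mean_shape, rate = params$mean_rate)
    de <- matrix(FALSE, nf, G)
    fac <- matrix(1, nf, G)
    for (g in seq_len(G)) {
      de[, g] <- stats::runif(nf) < params$de_prob[g]
      f <- exp(stats::rnorm(nf, params$de_fac_loc, params$de_fac_scale))
      flip <- stats::runif(nf) < 0.5
      f[flip] <- 1 / f[flip]
      fac[de[, g], g] <- f[de[, g]]
    }
    group_mean <- base_mean * fac                      # genes x groups
    group_prop <- sweep(group_mean, 2, colSums(group_mean), "/")
    group <- sample.int(G, params$batch_cells, replace = TRUE,
                        prob = params$group_prob)
    libsize <- stats::rlnorm(params$batch_cells, params$lib_loc, params$lib_scale)
    mu <- t(group_prop[, group, drop = FALSE]) * libsize   # cells x genes
    # mean-dependent BCV trend with inverse-chi-square gene scaling
    gene_scale <- sqrt(params$bcv_df / stats::rchisq(nf, df = params$bcv_df))
    bcv <- sweep(params$bcv_common + 1 / sqrt(pmax(mu, 1e-12)), 2, gene_scale, "*")
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = as.vector(1 / bcv^2)),
      nrow = params$batch_cells
    )
    fm <- feature_matrix(counts,
                         cell_ids = sprintf("cell_%04d", seq_len(params$batch_cells)),
                         feature_ids = sprintf("gene_%04d", seq_len(nf)),
                         modality = "RNA", is_raw_counts = TRUE)
    groups <- paste0("c", seq_len(G))
    dimnames(de) <- dimnames(fac) <- list(fm$feature_ids, groups)
    list(matrix = fm,
         truth = list(group = groups[group], de_genes = de, de_factor = fac,
                      params = params, seed = seed))
  })
}

#' Build conflicting annotation sets from ground-truth labels
#'
#' Applies a recipe of merge/split perturbations to the true group labels to
#' emulate under- and over-clustered annotation sets. A merge relabels the
#' listed groups to one joint label (`"c2+c3"`); a split partitions a
#' group's cells uniformly at random into numbered sub-labels (`"c5.1"`,
#' `"c5.2"`). Each recipe entry becomes one annotation column.
#'
#' @param truth_labels Character vector of true group labels per cell.
#' @param recipe Named list: one entry per annotation set, each a list of
#'   operations `list(merge = c("c1","c2"))` or `list(split = "c5")` (or
#'   `list(split = c("c2","c3"))` to split several groups in two). An empty
#'   list reproduces the truth.
#' @param cell_ids Cell ids for the output table.
#' @param seed Seed for the random splits.
#' @return Annotation tibble (`cell_id` + one column per recipe entry).
#' @export
perturb_annotations <- function(truth_labels, recipe, cell_ids, seed = 1L) {
  stopifnot(length(truth_labels) == length(cell_ids))
  truth_labels <- as.character(truth_labels)
  withr::with_seed(seed, {
    cols <- purrr::imap(recipe, function(ops, name) {
      lab <- truth_labels
      for (op in ops) {
        if (!is.null(op$merge)) {
          missing <- setdiff(op$merge, truth_labels)
          if (length(missing))
            stop("recipe references unknown groups: ",
                 paste(missing, collapse = ", "), call. = FALSE)
          lab[lab %in% op$merge] <- paste(op$merge, collapse = "+")
        }
        if (!is.null(op$split)) {
          for (g in op$split) {
            idx <- which(lab == g)
            if (!length(idx))
              stop("recipe references unknown group: ", g, call. = FALSE)
            half <- sample(c(1L, 2L), length(idx), replace = TRUE)
            lab[idx] <- paste0(g, ".", half)
          }
        }
      }
      lab
    })
    tibble::tibble(cell_id = cell_ids, !!!cols)
  })
}

#' Ready-made simulation fixtures with conflicting annotations
#'
#' Two benchmark scenarios of 3000 cells each. `"experiment1"` has 5 groups
#' (`group_prob = (0.23, 0.15, 0.15, 0.23, 0.24)`,
#' `de_prob = (0.15, 0.15, 0.15, 0.2, 0.4)`) and four annotation sets, none
#' equal to the truth: Broad (merges c1+c2+c3), Median (merges c2+c3), Fine
#' (randomly splits c5) and Excessive (randomly splits c2 and c3).
#' `"experiment2"` has 6 groups (`group_prob = (0.2, 0.2, 0.15, 0.15, 0.15,
#' 0.15)`) in which c3-c6 differ only subtly
#' (`de_prob = (0.2, 0.2, 0.005, 0.005, 0.005, 0.005)`), with Broad (merges
#' c3+c4+c5+c6), Median (merges c3+c4 and c5+c6) and Fine (equal to the
#' truth) annotations — the scenario that separates one- from two-order
#' TF-IDF scoring.
#'
#' The first fixture defaults to 2000 genes for tractability, with the
#' library-size location shifted by `ln(n_genes / 10000)` so that per-gene
#' sequencing depth — and hence the detection sparsity that the TF-IDF
#' metrics rely on — matches a full-size 10000-gene simulation. The second
#' fixture keeps all 10000 genes: its subtle groups are differential in only
#' 0.5% of genes, and the absolute number of exclusive markers available to
#' the 5th/10th-order exclusivity statistics is what separates them.
#'
#' @param name `"experiment1"` or `"experiment2"`.
#' @param seed Integer seed; the whole fixture is reproducible from it.
#' @param n_genes Number of simulated genes; defaults to 2000 for
#'   `"experiment1"` and 10000 for `"experiment2"`.
#' @return A list with `matrix` (raw counts), `annotations` (tibble) and
#'   `truth` (as in [simulate_counts()]).
#' @export
make_fixture <- function(name = c("experiment1", "experiment2"), seed = 1L,
                         n_genes = NULL) {
  name <- match.arg(name)
  if (is.null(n_genes)) n_genes <- if (name == "experiment1") 2000L else 10000L
  lib_loc <- 11 + log(n_genes / 10000)  # preserve per-gene depth
  if (name == "experiment1") {
    params <- sim_params(batch_cells = 3000L, n_genes = n_genes,
                         group_prob = c(0.23, 0.15, 0.15, 0.23, 0.24),
                         de_prob = c(0.15, 0.15, 0.15, 0.2, 0.4),
                         lib_loc = lib_loc)
    recipe <- list(
      Broad = list(list(merge = c("c1", "c2", "c3"))),
      Median = list(list(merge = c("c2", "c3"))),
      Fine = list(list(split = "c5")),
      Excessive = list(list(split = c("c2", "c3")))
    )
  } else {
    params <- sim_params(batch_cells = 3000L, n_genes = n_genes,
                         group_prob = c(0.2, 0.2, 0.15, 0.15, 0.15, 0.15),
                         de_prob = c(0.2, 0.2, 0.005, 0.005, 0.005, 0.005),
                         lib_loc = lib_loc)
    recipe <- list(
      Broad = list(list(merge = c("c3", "c4", "c5", "c6"))),
      Median = list(list(merge = c("c3", "c4")), list(merge = c("c5", "c6"))),
      Fine = list()
    )
  }
  sim <- simulate_counts(params, seed = seed)
  annotations <- perturb_annotations(sim$truth$group, recipe,
                                     cell_ids = sim$matrix$cell_ids,
                                     seed = seed + 1L)
  list(matrix = sim$matrix, annotations = annotations, truth = sim$truth)
}
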