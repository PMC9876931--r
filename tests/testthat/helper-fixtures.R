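# Programmatic fixtures shared across tests.

# normalized feature matrix with no structure (one homogeneous blob)
blob_matrix <- function(n_cells, n_features, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    feature_matrix(matrix(rnorm(n_cells * n_features, sd = sd), n_cells),
                   cell_ids = sprintf("b%03d", seq_len(n_cells)),
                   feature_ids = sprintf("f%03d", seq_len(n_features)),
                   modality = "RNA", is_raw_counts = FALSE)
  })
}

# k well-separated spherical clusters in feature space; returns list(fm, labels)
separated_clusters <- function(n_per = 30, n_features = 20, k = 2,
                               distance = 12, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(0, k, n_features)
    for (g in seq_len(k)) centers[g, g] <- distance
    labels <- rep(paste0("g", seq_len(k)), each = n_per)
    x <- centers[rep(seq_len(k), each = n_per), ] +
      matrix(rnorm(k * n_per * n_features), k * n_per)
    fm <- feature_matrix(x, cell_ids = sprintf("s%03d", seq_along(labels)),
                         feature_ids = sprintf("f%03d", seq_len(n_features)),
                         modality = "RNA", is_raw_counts = FALSE)
    list(fm = fm, labels = labels)
  })
}

# independent entropy oracle: homogeneity/completeness/v via the mutual
# information identity MI = H(C) + H(K) - H(C,K) (a different route than the
# package's conditional-entropy formulas)
oracle_agreement <- function(reference, prediction) {
  joint <- table(reference, prediction)
  ent <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
  hc <- ent(rowSums(joint)); hk <- ent(colSums(joint)); hck <- ent(as.vector(joint))
  mi <- hc + hk - hck
  h <- if (hc == 0) 1 else mi / hc
  c <- if (hk == 0) 1 else mi / hk
  v <- if (h + c == 0) 0 else 2 * h * c / (h + c)
  list(h = h, c = c, v = v)
}

# permutation-form Shapley oracle: average marginal surplus over all |A|!
# player orderings
oracle_shapley_permutation <- function(D, offset, adjustment) {
  A <- nrow(D)
  phi <- numeric(A)
  perms <- permutations_of(seq_len(A))
  for (ord in perms) {
    before <- integer(0)
    for (a in ord) {
      phi[a] <- phi[a] + coalition_surplus(D, a, before, offset, adjustment)
      before <- c(before, a)
    }
  }
  phi / length(perms)
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permutations_of(x[-i]), function(p) c(x[i], p)))
  out
}
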