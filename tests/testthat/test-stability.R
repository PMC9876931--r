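test_that("marker t-tests agree with a per-feature stats::t.test oracle", {
  withr::with_seed(11, {
    sep <- separated_clusters(n_per = 15, n_features = 12, k = 3, distance = 6)
  })
  mt <- rank_markers(sep$fm, sep$labels, top_markers = 12)
  for (cl in unique(sep$labels)) {
    idx <- sep$labels == cl
    p_oracle <- apply(sep$fm$values, 2, function(v)
      stats::t.test(v[idx], v[!idx])$p.value)
    lfc_oracle <- colMeans(sep$fm$values[idx, ]) - colMeans(sep$fm$values[!idx, ])
    sub <- mt[mt$cluster == cl, ]
    expect_equal(unname(sub$p_value[match(names(p_oracle), sub$feature)]),
                 unname(p_oracle), tolerance = 1e-10)
    expect_equal(unname(sub$lfc[match(names(lfc_oracle), sub$feature)]),
                 unname(lfc_oracle), tolerance = 1e-12)
    # the dominant injected feature is the unambiguous top marker
    top <- sub$feature[sub$position == 1]
    expect_equal(top, names(which.max(lfc_oracle)))
    expect_equal(unname(sub$r_combined[1]), 0)
  }
  expect_equal(mt$r_combined, (mt$r_pval + mt$r_lfc) / 2)
  expect_setequal(marker_union(mt), unique(mt$feature))
})

test_that("singleton clusters get worst p-value ranks with a warning", {
  fm <- blob_matrix(10, 6, seed = 2)
  labels <- c(rep("a", 9), "solo")
  expect_warning(mt <- rank_markers(fm, labels), "singleton")
  expect_true(all(mt$r_pval[mt$cluster == "solo"] == n_features(fm) - 1))
})

test_that("reassignment score is 1 in the separable limit and ~0.5 at chance", {
  sep <- separated_clusters(n_per = 40, n_features = 15, k = 2, distance = 15)
  sc <- reassign_score(sep$fm, sep$labels)
  expect_equal(unname(sc), c(1, 1))

  fm <- blob_matrix(1000, 10, seed = 13)
  withr::with_seed(14, labels <- sample(c("u", "v"), 1000, replace = TRUE))
  sc2 <- reassign_score(fm, labels)
  expect_true(all(sc2 >= 0 & sc2 <= 1))
  expect_true(all(abs(sc2 - 0.5) < 0.1))
})

test_that("nearest-centroid assignment matches an exhaustive distance scan", {
  withr::with_seed(15, {
    space <- matrix(rnorm(50 * 4), 50)
    labels <- sample(paste0("k", 1:3), 50, replace = TRUE)
  })
  got <- triangulatr:::nearest_centroid(space, labels)
  cents <- sapply(sort(unique(labels)), function(cl)
    colMeans(space[labels == cl, , drop = FALSE]))
  oracle <- apply(space, 1, function(row)
    colnames(cents)[which.min(colSums((cents - row)^2))])
  expect_equal(got, unname(oracle))
})

test_that("TF-IDF exclusivity follows the pseudo-valued formula", {
  eps <- 1e-5
  # feature a: expressed in all 4 cells of cluster "in", 4 of 10 cells overall
  vals <- matrix(0, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  vals[1:4, "a"] <- 1        # private to the cluster
  vals[, "b"] <- 1           # ubiquitous
  vals[5:6, "c"] <- 1        # absent from the cluster
  fm <- feature_matrix(vals, is_raw_counts = FALSE)
  labels <- c(rep("in", 4), rep("out", 6))
  excl <- tfidf_exclusivity(fm, labels, "in")
  expect_equal(unname(excl["RNA:a"]), (1 + eps) * -log(0.4 + eps),
               tolerance = 1e-12)
  expect_equal(unname(excl["RNA:b"]), (1 + eps) * -log(1 + eps),
               tolerance = 1e-12)
  expect_lt(excl["RNA:b"], 0)  # ubiquitous feature ~ -eps
  expect_gt(excl["RNA:b"], -2 * eps)
  # absent feature: eps * IDF, bounded by eps * (-log(eps))
  expect_equal(unname(excl["RNA:c"]), eps * -log(0.2 + eps), tolerance = 1e-12)
  expect_gte(excl["RNA:c"], 0)
  expect_lte(excl["RNA:c"], eps * -log(eps))
  # a perfect marker of a cluster covering fraction q scores (1+eps)(-ln(q+eps))
  q <- 0.4
  expect_equal(unname(excl["RNA:a"]), (1 + eps) * -log(q + eps), tolerance = 1e-12)
})

test_that("the TF-IDF(n) order statistic uses sorted-descending semantics", {
  expect_equal(tfidf_n_score(c(5, 4, 3, 2, 1), 5), 1)
  expect_equal(tfidf_n_score(c(2, 5, 1, 4, 3), 1), 5)
  expect_equal(tfidf_n_score(c(3, 3, 3), 2), 3)
  expect_equal(tfidf_n_score(c(7, 2), 10), 2)  # fewer features than n -> last
  # non-increasing in n for a fixed exclusivity profile
  withr::with_seed(16, e <- runif(30))
  scores <- sapply(1:30, tfidf_n_score, exclusivity = e)
  expect_true(all(diff(scores) <= 0))
})

test_that("cross-validated recall is 1 when separable, chance-level when not,
           and matches its own confusion matrix", {
  sep <- separated_clusters(n_per = 25, n_features = 10, k = 2, distance = 12)
  sc <- sccaf_score(sep$fm, sep$labels, seed = 5)
  expect_equal(unname(sc[sort(unique(sep$labels))]), c(1, 1))

  # on a homogeneous blob with random labels the classifier cannot beat
  # chance: pooled out-of-sample accuracy sits at 0.5 and so does the mean
  # recall (individual recalls trade off against each other through the
  # majority-class bias of a near-constant classifier)
  fm <- blob_matrix(1000, 8, seed = 17)
  withr::with_seed(18, labels <- sample(c("u", "v"), 1000, replace = TRUE))
  sc2 <- sccaf_score(fm, labels, seed = 5)
  expect_true(all(sc2 >= 0 & sc2 <= 1))
  psi2 <- attr(sc2, "confusion")
  expect_lt(abs(sum(diag(psi2)) / sum(psi2) - 0.5), 0.07)
  expect_lt(abs(mean(sc2) - 0.5), 0.1)

  # row recall recomputed from the pooled confusion counter
  sep3 <- separated_clusters(n_per = 10, n_features = 6, k = 3, distance = 4)
  sc3 <- sccaf_score(sep3$fm, sep3$labels, seed = 9)
  psi <- attr(sc3, "confusion")
  expect_equal(sum(psi), 30)
  expect_equal(unname(sc3[rownames(psi)]),
               unname(diag(psi) / rowSums(psi)))
  sc3t <- sccaf_score(sep3$fm, sep3$labels, seed = 9, variant = "trace")
  expect_equal(unname(sc3t[rownames(psi)]),
               unname(diag(attr(sc3t, "confusion")) / sum(diag(attr(sc3t, "confusion")))))
})

test_that("tiny and singleton clusters degrade gracefully", {
  fm <- blob_matrix(20, 6, seed = 19)
  labels <- c(rep("big", 16), rep("small", 3), "solo")
  expect_warning(expect_warning(sc <- sccaf_score(fm, labels, seed = 1),
                                "singleton"), "folds")
  expect_equal(unname(sc["solo"]), 0)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("compute_stability covers every (annotation, cluster, metric) and is
           invariant to cell order", {
  fx <- make_fixture("experiment1", seed = 21, n_genes = 80)
  fm <- normalize_cptt(fx$matrix)
  keep <- fx$matrix$cell_ids[1:250]
  sub <- feature_matrix(fm$values[keep, ], cell_ids = keep,
                        feature_ids = fm$feature_ids, modality = fm$modality,
                        is_raw_counts = FALSE)
  anno <- fx$annotations[match(keep, fx$annotations$cell_id),
                         c("cell_id", "Median", "Fine")]
  cfg <- run_config(random_seed = 2, tfidf_orders = c(10L, 5L))
  st <- compute_stability(sub, anno, cfg)
  expect_setequal(unique(st$metric), c("reassign", "tfidf10", "tfidf5", "sccaf"))
  counts <- dplyr::count(st, annotation, cluster)
  expect_true(all(counts$n == 4))
  expect_true(all(is.finite(st$score)))
  rng <- dplyr::filter(st, metric %in% c("reassign", "sccaf"))
  expect_true(all(rng$score >= 0 & rng$score <= 1))

  # permuting the cells changes no score
  perm <- withr::with_seed(23, sample(seq_along(keep)))
  sub2 <- feature_matrix(sub$values[perm, ], cell_ids = keep[perm],
                         feature_ids = sub$feature_ids, modality = sub$modality,
                         is_raw_counts = FALSE)
  st2 <- compute_stability(sub2, anno[perm, ], cfg)
  merged <- dplyr::inner_join(st, st2, by = c("annotation", "cluster", "metric"))
  expect_equal(merged$score.x, merged$score.y, tolerance = 1e-10)

  # default metric set is the three-score panel
  st3 <- compute_stability(sub, anno, run_config(random_seed = 2))
  expect_setequal(unique(st3$metric), c("reassign", "tfidf10", "sccaf"))

  # a duplicated annotation column yields identical score rows
  anno$Copy <- anno$Median
  st4 <- compute_stability(sub, anno, cfg)
  a <- dplyr::filter(st4, annotation == "Median") |> dplyr::arrange(cluster, metric)
  b <- dplyr::filter(st4, annotation == "Copy") |> dplyr::arrange(cluster, metric)
  expect_equal(a$score, b$score, tolerance = 1e-12)
})
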