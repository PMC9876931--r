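test_that("coalition surplus reproduces the hand-derived micro-cases", {
  # singleton coalition: trivially top for every metric
  D <- matrix(c(0.3, 0.9, 0.1), 1, 3)
  expect_equal(coalition_surplus(D, 1, integer(), offset = 0.01), 3)

  D <- matrix(c(1.0, 0.5), 2, 1)
  expect_equal(coalition_surplus(D, 1, 2L, offset = 0.01), 2)
  expect_equal(coalition_surplus(D, 2, 1L, offset = 0.01), 0)

  # the offset lifts each player past the other: both earn the full surplus
  D <- matrix(c(0.5, 0.505), 2, 1)
  expect_equal(coalition_surplus(D, 1, 2L, offset = 0.01), 2)
  expect_equal(coalition_surplus(D, 2, 1L, offset = 0.01), 2)
})

test_that("two-player Shapley values match full enumeration by hand", {
  D <- matrix(c(1.0, 0.5), 2, 1, dimnames = list(c("a1", "a2"), "m"))
  phi <- shapley_values(D, offset = 0.01)
  expect_equal(unname(phi), c(1.5, 0.5))
  # offset-induced tie: symmetric players, equal values
  D2 <- matrix(c(0.5, 0.505), 2, 1)
  phi2 <- shapley_values(D2, offset = 0.01)
  expect_equal(phi2[1], phi2[2])
})

test_that("exact enumeration equals the permutation-average oracle", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      A <- sample(2:6, 1); M <- sample(1:4, 1)
      D <- matrix(runif(A * M), A, M)
      adj <- sample(c("all_or_none", "classic"), 1)
      off <- sample(c(0, 0.01, 0.05), 1)
      expect_equal(unname(shapley_values(D, offset = off, adjustment = adj)),
                   oracle_shapley_permutation(D, off, adj),
                   tolerance = 1e-9)
    }
  })
})

test_that("symmetry and null-player axioms hold", {
  # equal score rows receive equal values
  withr::with_seed(32, D <- matrix(runif(4), 1, 4)[c(1, 1, 1), ])
  phi <- shapley_values(D, offset = 0.01)
  expect_true(max(phi) - min(phi) < 1e-12)

  # a strictly dominated player earns no credit beyond the trivial singleton
  # coalition (where any player is top by construction): its value is exactly
  # the floor M / A, and it is the unique minimum
  D2 <- rbind(c(1, 1), c(0.9, 0.9), c(0.1, 0.1))
  phi2 <- shapley_values(D2, offset = 0.01, adjustment = "all_or_none")
  expect_equal(unname(phi2[3]), 2 / 3)  # M = 2 metrics, A = 3 players
  expect_equal(which.min(phi2), 3L)
  # and values are invariant to metric order
  expect_equal(shapley_values(D2[, 2:1], offset = 0.01), phi2)
})

test_that("with offset 0 and strict ordering exactly one player attains max", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      A <- sample(2:5, 1)
      scores <- sort(runif(A), decreasing = TRUE)
      D <- matrix(rep(scores, 3), A, 3)  # metric-unanimous cell
      phi <- shapley_values(D, offset = 0)
      expect_equal(sum(phi == max(phi)), 1L)
      expect_equal(which.max(phi), 1L)
    }
  })
})

test_that("rank importance applies offset-tolerant ranks and adjustments", {
  D <- matrix(c(3, 2, 1), 3, 1)
  expect_equal(unname(rank_importance(D, "classic", offset = 0.01)), c(3, 2, 1))
  expect_equal(unname(rank_importance(D, "all_or_none", offset = 0.01)), c(3, 0, 0))
  D2 <- matrix(c(1.0, 0.995, 0.2), 3, 1)
  expect_equal(unname(rank_importance(D2, "all_or_none", offset = 0.01)), c(3, 3, 0))
})

test_that("winner assignment breaks ties toward the smaller source cluster", {
  anno <- tibble::tibble(cell_id = paste0("c", 1:160),
                         big = rep("B", 160),
                         small = rep(c("S1", "S2"), c(120, 40)))
  phi <- matrix(1, 160, 2, dimnames = list(NULL, c("big", "small")))
  w <- assign_winners(phi, anno)
  expect_true(all(w$winner_annotation == "small"))  # 40 < 120 < 160
  expect_equal(w$raw_label[160], "small@S2")

  # clear argmax wins regardless of size
  phi2 <- phi; phi2[, "big"] <- 2
  expect_true(all(assign_winners(phi2, anno)$winner_annotation == "big"))

  # tie of ties: equal sizes fall back to annotation name order
  anno3 <- tibble::tibble(cell_id = paste0("c", 1:10),
                          zeta = rep("z", 10), alpha = rep("a", 10))
  phi3 <- matrix(1, 10, 2, dimnames = list(NULL, c("zeta", "alpha")))
  expect_true(all(assign_winners(phi3, anno3)$winner_annotation == "alpha"))
})

test_that("cluster quality is normalized by players and clusters", {
  q <- cluster_quality(rep(2, 10), rep("a@x", 10), n_players = 1)
  expect_equal(q$quality, 2)
  # duplicating identical players does not inflate quality: with A duplicated
  # annotations every coalition rank is tied at the top, so phi grows with A
  # but the normalization divides it back out
  anno <- tibble::tibble(cell_id = paste0("c", 1:20),
                         a1 = rep(c("x", "y"), 10))
  st <- tibble::tibble(annotation = "a1", cluster = c("x", "y"),
                       metric = "m1", score = c(0.8, 0.6))
  fm <- blob_matrix(20, 5, seed = 3)
  fm$cell_ids <- anno$cell_id
  rownames(fm$values) <- anno$cell_id
  phi1 <- triangulatr:::cell_importance(st, anno, "a1", "m1",
                                        run_config(), "shapley")
  q1 <- cluster_quality(phi1[, 1], paste0("a1@", anno$a1), 1)
  anno2 <- dplyr::mutate(anno, a2 = a1, a3 = a1)
  st2 <- dplyr::bind_rows(st, dplyr::mutate(st, annotation = "a2"),
                          dplyr::mutate(st, annotation = "a3"))
  phi3 <- triangulatr:::cell_importance(st2, anno2, c("a1", "a2", "a3"), "m1",
                                        run_config(), "shapley")
  q3 <- cluster_quality(phi3[, 1], paste0("a1@", anno$a1), 3)
  expect_lte(mean(q3$quality), mean(q1$quality) + 1e-9)
  expect_true(all(q1$quality >= 0) && all(q3$quality >= 0))
})
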