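# Coalitional scoring of annotation sets.
#
# Each annotation set is a "player"; its payoff inside a coalition is driven
# by how its per-cluster stability scores rank against the other members,
# with an additive tolerance (`offset`) letting near-equal scores share the
# top rank. The Shapley value of a player is the weighted average of its
# marginal surplus over all coalitions and is computed by exact subset
# enumeration, which is tractable for the usual handful of annotation sets.

# offset-tolerant ascending ranks within a coalition: rank of player p is the
# number of members whose score does not exceed score_p + offset (ties at the
# top therefore share the maximal rank |S|)
offset_ranks <- function(scores, offset) {
  vapply(seq_along(scores),
         function(p) sum(scores <= scores[p] + offset),
         numeric(1))
}

#' Marginal surplus of an annotation joining a coalition
#'
#' Implements the value-function difference `V(T u {a}) - V(T)` of the
#' coalitional game. For each stability metric, the focal player's score plus
#' the tolerance `offset` is ranked against the scores of the coalition it
#' joins; under the default `all_or_none` adjustment the player earns the
#' coalition size `|T u {a}|` whenever it (co-)holds the top rank and nothing
#' otherwise, while `classic` credits its offset-adjusted rank as is. The
#' offset is applied to the focal player only.
#'
#' @param D Numeric matrix, annotation sets x metrics, holding each player's
#'   per-metric stability score for the cluster the cell belongs to.
#' @param a Index of the focal player (row of `D`).
#' @param coalition Integer indices of the players already in the coalition
#'   (must not include `a`); may be empty.
#' @param offset Rank tolerance.
#' @param adjustment `"all_or_none"` or `"classic"`.
#' @return The surplus, a single non-negative number.
#' @export
coalition_surplus <- function(D, a, coalition = integer(), offset = 0.01,
                              adjustment = c("all_or_none", "classic")) {
  adjustment <- match.arg(adjustment)
  stopifnot(!a %in% coalition)
  size <- length(coalition) + 1L
  v <- 0
  for (m in seq_len(ncol(D))) {
    rank_a <- 1L + sum(D[coalition, m] <= D[a, m] + offset)
    v <- v + switch(adjustment,
                    all_or_none = if (rank_a == size) size else 0,
                    classic = rank_a)
  }
  v
}

#' Exact Shapley values of annotation sets for one cell
#'
#' Enumerates every coalition `T` not containing player `a` and averages the
#' marginal surplus `V(T u {a}) - V(T)` with the standard combinatorial
#' weight `|T|! (A - |T| - 1)! / A!`. With the default winner-take-all value
#' function the computation per player touches all `2^(A-1)` subsets, so the
#' player count is capped; beyond the cap use [rank_importance()].
#'
#' @param D Numeric matrix, annotation sets x metrics (a cell's stability
#'   score profile).
#' @param offset Rank tolerance (see [coalition_surplus()]).
#' @param adjustment Rank adjustment passed to [coalition_surplus()].
#' @param max_players Hard cap on exact enumeration.
#' @return Numeric vector of Shapley values, named by `rownames(D)`.
#' @export
shapley_values <- function(D, offset = 0.01,
                           adjustment = c("all_or_none", "classic"),
                           max_players = 20L) {
  adjustment <- match.arg(adjustment)
  A <- nrow(D)
  if (A > max_players)
    stop("exact Shapley enumeration capped at ", max_players,
         " annotation sets; use rank_importance()", call. = FALSE)
  fact <- factorial(0:A)  # exact for the player counts enumeration allows
  phi <- numeric(A)
  for (a in seq_len(A)) {
    others <- setdiff(seq_len(A), a)
    for (mask in 0:(2^(A - 1L) - 1L)) {
      coalition <- others[bitwAnd(mask, 2^(seq_len(A - 1L) - 1L)) > 0L]
      t_size <- length(coalition)
      w <- fact[t_size + 1] * fact[A - t_size] / fact[A + 1]
      phi[a] <- phi[a] +
        w * coalition_surplus(D, a, coalition, offset, adjustment)
    }
  }
  stats::setNames(phi, rownames(D))
}

#' Rank-based annotation importance
#'
#' The fast alternative to Shapley enumeration used when many annotation sets
#' are supplied: each player is ranked within the single grand coalition per
#' metric (offset-tolerant, ascending, ties share the top rank) and its
#' importance is the sum of ranks across metrics. Under `all_or_none` every
#' non-top rank is zeroed first, so only metric winners accumulate credit.
#'
#' @inheritParams shapley_values
#' @return Numeric vector of importances, named by `rownames(D)`.
#' @export
rank_importance <- function(D, adjustment = c("all_or_none", "classic"),
                            offset = 0.01) {
  adjustment <- match.arg(adjustment)
  A <- nrow(D)
  imp <- numeric(A)
  for (m in seq_len(ncol(D))) {
    r <- offset_ranks(D[, m], offset)
    if (adjustment == "all_or_none") r[r < max(r)] <- 0
    imp <- imp + r
  }
  stats::setNames(imp, rownames(D))
}

#' Assign each cell to its most important annotation
#'
#' Applies `argmax_a phi_a(i)` per cell. Exact ties are broken in favour of
#' the annotation whose originating cluster (the cell's cluster in that
#' annotation set) is smaller — the more specific population — and, should
#' sizes tie as well, by annotation name, making the assignment
#' deterministic. The raw label is `"<annotation>@<cluster>"`.
#'
#' @param phi Numeric matrix, cells x annotation sets, of importances; column
#'   names are the annotation names.
#' @param annotations Annotation tibble (`cell_id` + one column per set) in
#'   the same cell order.
#' @return Tibble with columns `cell_id`, `winner_annotation`, `raw_label`.
#' @export
assign_winners <- function(phi, annotations) {
  anno_names <- colnames(phi)
  stopifnot(all(anno_names %in% colnames(annotations)),
            nrow(phi) == nrow(annotations))
  # size of each (annotation, label) originating cluster
  sizes <- lapply(anno_names, function(a) table(annotations[[a]]))
  names(sizes) <- anno_names
  winner <- character(nrow(phi))
  for (i in seq_len(nrow(phi))) {
    top <- which(phi[i, ] == max(phi[i, ]))
    if (length(top) > 1L) {
      sz <- vapply(anno_names[top], function(a)
        as.integer(sizes[[a]][[annotations[[a]][i]]]), integer(1))
      top <- top[order(sz, anno_names[top])][1]
    }
    winner[i] <- anno_names[top[1]]
  }
  labels <- vapply(seq_along(winner),
                   function(i) annotations[[winner[i]]][i], character(1))
  tibble::tibble(cell_id = annotations$cell_id,
                 winner_annotation = winner,
                 raw_label = paste0(winner, "@", labels))
}

#' Average-importance quality of winner clusters
#'
#' An Elo-like rating of each winner cluster: the mean winning importance of
#' its cells, normalized by the number of players (importance grows
#' additively with the player count) and by the number of winner clusters.
#' Comparable across runs with different numbers of annotation sets.
#'
#' @param phi_winner Numeric vector: each cell's importance under its winning
#'   annotation.
#' @param raw_labels Character vector of raw winner labels, one per cell.
#' @param n_players Number of annotation sets in the game.
#' @return Tibble with columns `raw_label` and `quality`.
#' @export
cluster_quality <- function(phi_winner, raw_labels, n_players) {
  n_clusters <- dplyr::n_distinct(raw_labels)
  tibble::tibble(raw_label = raw_labels, phi = phi_winner) |>
    dplyr::summarise(quality = mean(.data$phi) / n_players / n_clusters,
                     .by = "raw_label")
}
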