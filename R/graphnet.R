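#' Build a complete weighted aptamer network
#'
#' Every aptamer becomes a vertex carrying its group label (typically role x
#' context, e.g. `"apt1/GCV"`); every unordered pair becomes an edge weighted
#' by the similarity matrix entry.  The graph is complete (`n(n-1)/2` edges,
#' no self-loops) until thresholded.
#'
#' @param matrix a [similarity_matrix()].
#' @param group_labels named character vector: id -> group; must cover every
#'   id in the matrix exactly.
#' @return object of class `"aptamer_network"`: list(graph, higher_is_similar).
#' @export
build_network <- function(matrix, group_labels) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  unlabeled <- setdiff(matrix$ids, names(group_labels))
  if (length(unlabeled))
    stop("id(s) without a group label: ", paste(unlabeled, collapse = ", "))
  extra <- setdiff(names(group_labels), matrix$ids)
  if (length(extra))
    stop("group label(s) without a matrix id: ", paste(extra, collapse = ", "))
  g <- igraph::graph_from_adjacency_matrix(matrix$values, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$group <- unname(group_labels[igraph::V(g)$name])
  structure(list(graph = g, higher_is_similar = matrix$higher_is_similar),
            class = "aptamer_network")
}

#' Trim a network at an edge-weight threshold
#'
#' For similarity-like metrics an edge survives iff `weight >= t`; for
#' distance-like metrics iff `weight <= t`.  Boundary edges (weight exactly
#' `t`) survive.  All vertices are kept.
#'
#' @param network an [build_network()] object.
#' @param t threshold value on the metric's own scale.
#' @return object of class `"thresholded_graph"`:
#'   list(graph, threshold, higher_is_similar).
#' @export
threshold_graph <- function(network, t) {
  stopifnot(inherits(network, "aptamer_network"))
  w <- igraph::E(network$graph)$weight
  drop <- if (network$higher_is_similar) which(w < t) else which(w > t)
  g <- igraph::delete_edges(network$graph, drop)
  structure(list(graph = g, threshold = t,
                 higher_is_similar = network$higher_is_similar),
            class = "thresholded_graph")
}

group_vertices <- function(tg, group) {
  v <- which(igraph::V(tg$graph)$group == group)
  if (!length(v)) stop("no vertices in group '", group, "'")
  v
}

#' Intra-group edge density of a thresholded network
#'
#' Fraction of the `choose(n, 2)` possible within-group edges that survived
#' thresholding.
#'
#' @param tg a [threshold_graph()] object.
#' @param group group label (>= 2 members).
#' @return density in `[0, 1]`.
#' @export
intra_density <- function(tg, group) {
  v <- group_vertices(tg, group)
  n <- length(v)
  if (n < 2) stop("intra_density needs a group of size >= 2, got ", n)
  sub <- igraph::induced_subgraph(tg$graph, v)
  igraph::ecount(sub) / choose(n, 2)
}

#' Inter-group edge density of a thresholded network
#'
#' Fraction of the `n_a * n_b` possible cross edges between two disjoint
#' groups that survived thresholding.  Within-group edges never count.
#'
#' @param tg a [threshold_graph()] object.
#' @param group_a,group_b disjoint non-empty group labels.
#' @return density in `[0, 1]`; symmetric in its group arguments.
#' @export
inter_density <- function(tg, group_a, group_b) {
  if (identical(group_a, group_b))
    stop("inter_density needs two distinct groups")
  va <- group_vertices(tg, group_a)
  vb <- group_vertices(tg, group_b)
  ends <- igraph::ends(tg$graph, igraph::E(tg$graph), names = FALSE)
  cross <- (ends[, 1] %in% va & ends[, 2] %in% vb) |
           (ends[, 1] %in% vb & ends[, 2] %in% va)
  sum(cross) / (length(va) * length(vb))
}

#' Edge-weight multiset within a group or between two groups
#'
#' Returns the un-thresholded weights of all within-group edges (one group)
#' or all cross edges (two groups), for downstream statistics such as
#' [wilcoxon_rank_sum()].
#'
#' @param network an [build_network()] object.
#' @param group_a group label.
#' @param group_b optional second group label; if supplied, cross weights.
#' @return numeric vector of edge weights.
#' @export
group_edge_weights <- function(network, group_a, group_b = NULL) {
  g <- network$graph
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  grp <- igraph::V(g)$group
  if (is.null(group_b)) {
    sel <- grp[ends[, 1]] == group_a & grp[ends[, 2]] == group_a
  } else {
    sel <- (grp[ends[, 1]] == group_a & grp[ends[, 2]] == group_b) |
           (grp[ends[, 1]] == group_b & grp[ends[, 2]] == group_a)
  }
  igraph::E(g)$weight[sel]
}

#' Intra- and inter-group density across a threshold sweep
#'
#' For every threshold, the network is trimmed and the surviving-edge
#' densities recounted for each group (intra) and each requested group pair
#' (inter).  For a similarity-like metric each density series is the
#' complementary cumulative distribution of the relevant edge-weight
#' multiset, hence non-increasing in the threshold.
#'
#' @param network an [build_network()] object.
#' @param thresholds sorted numeric vector of thresholds.
#' @param groups group labels for intra densities; defaults to all groups
#'   with >= 2 members.
#' @param pairs optional list of 2-element character vectors for inter
#'   densities.
#' @return data.frame of class `"density_curve"` with columns threshold,
#'   type (intra/inter), group, n_possible, n_surviving, density.
#' @export
density_curve <- function(network, thresholds, groups = NULL, pairs = NULL) {
  stopifnot(inherits(network, "aptamer_network"))
  if (is.unsorted(thresholds)) stop("thresholds must be sorted increasingly")
  allgrp <- igraph::V(network$graph)$group
  if (is.null(groups)) {
    tab <- table(allgrp)
    groups <- names(tab)[tab >= 2]
  }
  rows <- list()
  for (t in thresholds) {
    tg <- threshold_graph(network, t)
    for (grp in groups) {
      n <- sum(allgrp == grp)
      poss <- choose(n, 2)
      d <- intra_density(tg, grp)
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = t, type = "intra", group = grp,
        n_possible = poss, n_surviving = round(d * poss), density = d)
    }
    for (pr in pairs) {
      poss <- sum(allgrp == pr[1]) * sum(allgrp == pr[2])
      d <- inter_density(tg, pr[1], pr[2])
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = t, type = "inter", group = paste(pr, collapse = "|"),
        n_possible = poss, n_surviving = round(d * poss), density = d)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("density_curve", "data.frame")
  out
}
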