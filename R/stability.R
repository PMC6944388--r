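#' Configuration of the parametric edge-perturbation bootstrap
#'
#' Each replicate replaces a fixed fraction of the network's edges: `k`
#' existing edges are removed and `k` previously absent edges added
#' (`k = max(1, round(fraction * |E|))`), so the node set and edge count are
#' preserved but `fraction` of the edges connect different nodes.
#'
#' @param perturb_fraction fraction of edges replaced per replicate.
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed; every replicate's RNG state derives from it.
#' @return list of class `"stability_config"`.
#' @export
stability_config <- function(perturb_fraction = 0.05, replicates = 100L,
                             seed = 1L) {
  stopifnot(perturb_fraction > 0, perturb_fraction < 1, replicates >= 1)
  structure(list(perturb_fraction = perturb_fraction,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "stability_config")
}

#' Randomly replace a fraction of a thresholded graph's edges
#'
#' Removes `k = max(1, round(fraction * |E|))` distinct edges uniformly at
#' random and adds `k` distinct edges drawn uniformly from the pairs absent
#' in the input graph (no self-loops, never re-adding a just-removed edge),
#' so the perturbed graph has the same nodes and the same number of edges
#' and its edge set differs from the input's by exactly `2k`.
#'
#' Uses R's global random number generator; seed it for reproducibility.
#'
#' @param tg a [threshold_graph()] object.
#' @param fraction fraction of edges to replace.
#' @return a perturbed `"thresholded_graph"` (carries `k_replaced`).
#' @export
perturb <- function(tg, fraction = 0.05) {
  stopifnot(inherits(tg, "thresholded_graph"))
  g <- tg$graph
  ne <- igraph::ecount(g)
  n <- igraph::vcount(g)
  if (ne < 1) stop("perturb needs a graph with at least one edge")
  k <- max(1L, round(fraction * ne))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  non <- which(upper.tri(adj) & !adj)
  if (k > length(non))
    stop("cannot add ", k, " edges: only ", length(non), " non-edges available")
  removed <- sample(ne, k)
  added <- non[sample(length(non), k)]
  ai <- ((added - 1) %% n) + 1   # row index of upper-tri linear index
  aj <- ((added - 1) %/% n) + 1
  g2 <- igraph::delete_edges(g, removed)
  g2 <- igraph::add_edges(g2, rbind(ai, aj))
  structure(list(graph = g2, threshold = tg$threshold,
                 higher_is_similar = tg$higher_is_similar, k_replaced = k),
            class = "thresholded_graph")
}

#' Cluster stability under the edge-perturbation bootstrap
#'
#' Per replicate: perturb the graph, re-run the community detection
#' algorithm, find the community best matching the original cluster by
#' Jaccard similarity, and record that Jaccard.  The mean over replicates is
#' the stability of the cluster under the given algorithm.  Fully
#' reproducible: replicate `r` reseeds the RNG deterministically from
#' `config$seed`.
#'
#' @param tg a [threshold_graph()] object (the unperturbed network).
#' @param original_cluster character vector of node ids (subset of the
#'   graph's nodes).
#' @param algorithm one of [community_algorithms()].
#' @param config a [stability_config()].
#' @return object of class `"stability_report"`: list(algorithm,
#'   mean_jaccard, jaccard (per replicate), k_replaced, seed).
#' @export
bootstrap_stability <- function(tg, original_cluster,
                                algorithm = "greedy_modularity",
                                config = stability_config()) {
  stopifnot(inherits(tg, "thresholded_graph"))
  unknown <- setdiff(original_cluster, igraph::V(tg$graph)$name)
  if (length(unknown))
    stop("original_cluster contains unknown node(s): ",
         paste(unknown, collapse = ", "))
  jac <- numeric(config$replicates)
  kr <- integer(config$replicates)
  for (r in seq_len(config$replicates)) {
    set.seed((config$seed + 7919L * r) %% 2147483647L)
    ptg <- perturb(tg, config$perturb_fraction)
    kr[r] <- ptg$k_replaced
    part <- detect(ptg, algorithm)
    jac[r] <- match_communities(list(part), original_cluster)[[1]]$jaccard
  }
  structure(list(algorithm = algorithm, mean_jaccard = mean(jac),
                 jaccard = jac, k_replaced = kr, seed = config$seed),
            class = "stability_report")
}

#' @export
as.data.frame.stability_report <- function(x, ...) {
  data.frame(algorithm = x$algorithm,
             replicate = seq_along(x$jaccard),
             jaccard = x$jaccard,
             k_replaced = x$k_replaced,
             seed = x$seed)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report:", x$algorithm, "-", length(x$jaccard),
      "replicates, mean Jaccard", round(x$mean_jaccard, 4), "\n")
  invisible(x)
}
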