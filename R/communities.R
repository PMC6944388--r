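#' Community detection algorithms available for consensus clustering
#' @return character vector of algorithm names accepted by [detect()].
#' @export
community_algorithms <- function() {
  c("greedy_modularity", "random_walk", "edge_betweenness",
    "leading_eigenvector")
}

#' Detect communities on a thresholded graph
#'
#' Thin, name-stable front end over igraph's community detection: greedy
#' modularity agglomeration, Walktrap random walks (length 4), edge
#' betweenness, and leading-eigenvector bisection.  Detection runs on the
#' thresholded topology with edges unweighted, so the object clustered is the
#' same one the stability bootstrap perturbs.  Isolated vertices come back as
#' singleton communities.  A returned partition whose modularity falls below
#' that of the trivial connected-components partition is replaced by the
#' latter, which keeps degenerate inputs (a single clique, a complete graph)
#' from being split on dendrogram-cut ties.
#'
#' @param tg a [threshold_graph()] object (or an igraph graph).
#' @param algorithm one of [community_algorithms()].
#' @return object of class `"community_partition"`: list(algorithm,
#'   membership) where membership is a named integer vector with dense
#'   community indices from 0.
#' @export
detect <- function(tg, algorithm = "greedy_modularity") {
  g <- if (inherits(tg, "thresholded_graph")) tg$graph else tg
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  if (!algorithm %in% community_algorithms())
    stop("unknown community detection algorithm: ", algorithm)
  if (igraph::ecount(g) == 0) {  # degenerate: every vertex its own community
    dense <- seq_len(igraph::vcount(g)) - 1L
    names(dense) <- igraph::V(g)$name
    return(structure(list(algorithm = algorithm, membership = dense),
                     class = "community_partition"))
  }
  cl <- switch(algorithm,
    greedy_modularity = igraph::cluster_fast_greedy(g),
    random_walk = igraph::cluster_walktrap(g, steps = 4),
    edge_betweenness = igraph::cluster_edge_betweenness(g),
    leading_eigenvector = igraph::cluster_leading_eigen(g),
    stop("unknown community detection algorithm: ", algorithm)
  )
  mem <- igraph::membership(cl)
  # guard against degenerate dendrogram cuts (e.g. fast-greedy splitting a
  # lone vertex off a complete graph): never accept a partition with lower
  # modularity than the trivial connected-components partition
  comp <- igraph::components(g)$membership
  if (igraph::modularity(g, mem) < igraph::modularity(g, comp))
    mem <- comp
  dense <- as.integer(factor(mem, levels = unique(mem))) - 1L
  names(dense) <- igraph::V(g)$name
  structure(list(algorithm = algorithm, membership = dense),
            class = "community_partition")
}

#' Communities of a partition as a list of node-id sets
#' @param partition a [detect()] result.
#' @return list of character vectors, ordered by community index.
#' @export
partition_communities <- function(partition) {
  m <- partition$membership
  lapply(sort(unique(m)), function(k) names(m)[m == k])
}

#' Jaccard similarity of two node sets
#'
#' `|A n B| / |A u B|`; two empty sets count as identical (1).
#'
#' @param set_a,set_b character vectors of node ids.
#' @return value in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  u <- length(union(set_a, set_b))
  if (u == 0) return(1)
  length(intersect(set_a, set_b)) / u
}

#' Best-matching community per partition for a reference node set
#'
#' For each partition, the community maximising Jaccard similarity with the
#' reference set.  Ties are broken toward the smaller community, then toward
#' the community whose lexicographically smallest member id is smallest.
#'
#' @param partitions list of [detect()] results.
#' @param reference_community character vector of node ids.
#' @return list (one element per partition) of list(community, jaccard).
#' @export
match_communities <- function(partitions, reference_community) {
  lapply(partitions, function(p) {
    comms <- partition_communities(p)
    jac <- vapply(comms, jaccard, numeric(1), set_b = reference_community)
    sizes <- lengths(comms)
    firsts <- vapply(comms, function(cm) min(cm), character(1))
    best <- order(-jac, sizes, firsts)[1]
    list(community = comms[[best]], jaccard = jac[best])
  })
}

#' Consensus core clusters across several community partitions
#'
#' Formalises the "core cluster present in all algorithms" rule: seed
#' communities come from the first partition; for each seed, the
#' best-Jaccard-matching community is found in every partition and their
#' intersection is the core (kept when it has at least `min_core_size`
#' members).  A node's votes count the partitions whose matching community
#' contains it; nodes with votes from at least `ceiling(vote_fraction * k)`
#' of the `k` partitions join the augmented cluster.  Clusters with
#' identical cores are reported once.
#'
#' @param partitions list of >= 2 [detect()] results over the same node set.
#' @param min_core_size minimum core size to report a cluster.
#' @param vote_fraction fraction of algorithms required for augmentation.
#' @return list of objects of class `"consensus_cluster"`: list(core,
#'   augmented, votes) with `core` a subset of `augmented` and `votes` a
#'   named integer vector over the augmented nodes.
#' @export
consensus_core <- function(partitions, min_core_size = 3,
                           vote_fraction = 0.5) {
  if (length(partitions) < 2)
    stop("consensus_core needs at least two partitions")
  nodesets <- lapply(partitions, function(p) sort(names(p$membership)))
  if (!all(vapply(nodesets[-1], identical, logical(1), nodesets[[1]])))
    stop("partitions cover different node sets")
  k <- length(partitions)
  need <- ceiling(vote_fraction * k)
  out <- list()
  seen_cores <- character()
  for (seed in partition_communities(partitions[[1]])) {
    matches <- match_communities(partitions, seed)
    core <- Reduce(intersect, lapply(matches, `[[`, "community"))
    if (length(core) < min_core_size) next
    key <- paste(sort(core), collapse = "\r")
    if (key %in% seen_cores) next
    seen_cores <- c(seen_cores, key)
    votes <- table(unlist(lapply(matches, `[[`, "community")))
    votes <- stats::setNames(as.integer(votes), names(votes))
    augmented <- sort(union(core, names(votes)[votes >= need]))
    out[[length(out) + 1L]] <- structure(
      list(core = sort(core), augmented = augmented,
           votes = votes[augmented]),
      class = "consensus_cluster")
  }
  out
}
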