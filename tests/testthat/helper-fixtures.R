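# In-code fixtures shared across test files.

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a random symmetric similarity matrix over n labelled nodes
random_sim_matrix <- function(n, seed = 1, lo = 0, hi = 100) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  w <- runif(n * (n - 1) / 2, lo, hi)
  m[upper.tri(m)] <- w
  m <- m + t(m)
  diag(m) <- 100
  similarity_matrix(m, "random", higher_is_similar = TRUE)
}

# wrap an igraph graph as a thresholded_graph for direct module testing
as_tg <- function(g, threshold = 0) {
  structure(list(graph = g, threshold = threshold, higher_is_similar = TRUE),
            class = "thresholded_graph")
}

# c cliques of size k, consecutive cliques joined by a single bridge edge
clique_graph <- function(k = 10, c = 2, bridge = TRUE) {
  g <- igraph::make_empty_graph(n = k * c, directed = FALSE)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(k * c))
  for (ci in seq_len(c)) {
    nodes <- (ci - 1) * k + seq_len(k)
    g <- igraph::add_edges(g, combn(nodes, 2))
  }
  if (bridge && c > 1) {
    for (ci in seq_len(c - 1))
      g <- igraph::add_edges(g, c(ci * k, ci * k + 1))
  }
  g
}

clique_members <- function(k, ci) sprintf("v%02d", (ci - 1) * k + seq_len(k))

# minimal hit table builder
hit_row <- function(id, start, end, contig = "c1", strand = "+",
                    evalue = 1e-10) {
  data.frame(id = id, contig = contig, start = start, end = end,
             strand = strand, evalue = evalue, stringsAsFactors = FALSE)
}
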