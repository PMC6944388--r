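test_that("all four algorithms split two bridged cliques", {
  g <- clique_graph(k = 5, c = 2)
  tg <- as_tg(g)
  for (alg in community_algorithms()) {
    p <- detect(tg, alg)
    comms <- partition_communities(p)
    expect_equal(length(comms), 2, info = alg)
    expect_setequal(comms[[which(vapply(comms, function(x)
      "v01" %in% x, logical(1)))]], clique_members(5, 1))
  }
  # the clique split beats random partitions on modularity
  set.seed(31)
  mod_split <- igraph::modularity(g, rep(1:2, each = 5))
  rand <- replicate(200, igraph::modularity(g, sample(1:2, 10, TRUE)))
  expect_true(all(mod_split >= rand))
})

test_that("degenerate graphs give one community or all singletons", {
  single <- clique_graph(k = 6, c = 1)
  for (alg in community_algorithms())
    expect_equal(length(partition_communities(detect(as_tg(single), alg))), 1)
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(empty)$name <- letters[1:5]
  p <- detect(as_tg(empty), "greedy_modularity")
  expect_equal(unname(p$membership), 0:4)
  expect_error(detect(as_tg(empty), "no_such_method"), "unknown")
})

test_that("detection is stable under vertex relabelling", {
  g <- clique_graph(k = 4, c = 3)
  perm <- c(7, 1, 12, 3, 9, 5, 11, 2, 8, 4, 10, 6)
  gp <- igraph::permute(g, perm)
  for (alg in c("greedy_modularity", "random_walk")) {
    p1 <- detect(as_tg(g), alg)
    p2 <- detect(as_tg(gp), alg)
    sets1 <- lapply(partition_communities(p1), sort)
    sets2 <- lapply(partition_communities(p2), sort)
    expect_setequal(sets1, sets2)
  }
})

test_that("community matching maximises Jaccard with fixed tie-breaks", {
  part <- function(sets) {
    mem <- integer(0)
    for (i in seq_along(sets))
      mem <- c(mem, stats::setNames(rep(i - 1L, length(sets[[i]])),
                                    sets[[i]]))
    structure(list(algorithm = "manual", membership = mem),
              class = "community_partition")
  }
  p1 <- part(list(c("a", "b", "c"), c("d", "e")))
  m1 <- match_communities(list(p1), c("a", "b", "c"))[[1]]
  expect_setequal(m1$community, c("a", "b", "c"))
  expect_equal(m1$jaccard, 1)

  p2 <- part(list(c("a", "b"), c("c", "d")))
  m2 <- match_communities(list(p2), c("a", "b", "c"))[[1]]
  expect_setequal(m2$community, c("a", "b"))  # 2/3 beats 1/4
  expect_equal(m2$jaccard, 2 / 3)

  p3 <- part(list(c("x", "y", "z"), c("u", "v")))
  m3 <- match_communities(list(p3), c("a", "b"))[[1]]
  expect_equal(m3$jaccard, 0)
  expect_setequal(m3$community, c("u", "v"))  # tie at 0: smaller community
})

test_that("consensus cores intersect matches and votes gate augmentation", {
  part <- function(sets) {
    mem <- integer(0)
    for (i in seq_along(sets))
      mem <- c(mem, stats::setNames(rep(i - 1L, length(sets[[i]])),
                                    sets[[i]]))
    structure(list(algorithm = "manual", membership = mem),
              class = "community_partition")
  }
  nodes <- c("a", "b", "c", "x", "y", "q", "r", "s")
  # all four partitions agree on {a,b,c}; x co-clusters in 2/4, y in 1/4
  p <- list(
    part(list(c("a", "b", "c", "x"), c("y", "q", "r", "s"))),
    part(list(c("a", "b", "c", "x", "y"), c("q", "r", "s"))),
    part(list(c("a", "b", "c"), c("x", "y", "q", "r", "s"))),
    part(list(c("a", "b", "c"), c("x", "y"), c("q", "r", "s"))))
  cl <- consensus_core(p)
  target <- cl[[which(vapply(cl, function(x) "a" %in% x$core, logical(1)))]]
  expect_identical(target$core, c("a", "b", "c"))
  expect_true("x" %in% target$augmented)   # 2 of 4 votes
  expect_false("y" %in% target$augmented)  # 1 of 4 votes
  expect_equal(unname(target$votes[c("a", "x")]), c(4L, 2L))

  # raising the vote requirement never adds nodes
  stricter <- consensus_core(p, vote_fraction = 0.75)
  t2 <- stricter[[which(vapply(stricter, function(x) "a" %in% x$core,
                               logical(1)))]]
  expect_true(all(t2$augmented %in% target$augmented))
  expect_false("x" %in% t2$augmented)

  # full agreement: core equals augmented equals the common community
  agree <- list(part(list(c("a", "b", "c"), c("x", "y", "q", "r", "s"))),
                part(list(c("a", "b", "c"), c("x", "y", "q", "r", "s"))))
  cl2 <- consensus_core(agree)
  expect_identical(cl2[[1]]$core, cl2[[1]]$augmented)

  expect_error(consensus_core(p[1]), "at least two")
  mismatched <- part(list(c("a", "b", "zz")))
  expect_error(consensus_core(list(p[[1]], mismatched)), "different node sets")
})

test_that("consensus recovers planted groups on a synthetic cohort", {
  co <- generate_cohort(cohort_params(seed = 5, n_tandem_per_context = 10,
                                      n_singleton_per_context = 5))
  sm <- pairwise_matrix(co$sequences)
  groups <- truth_groups(co$truth)
  net <- build_network(sm, groups)
  tg <- threshold_graph(net, 85)
  parts <- lapply(community_algorithms(), function(a) detect(tg, a))
  cl <- consensus_core(parts)
  for (ctx in c("GCV", "TP")) {
    apt <- if (ctx == "GCV") "apt1" else "apt2"
    sing <- if (ctx == "GCV") "sing1" else "sing2"
    planted <- names(groups)[groups %in% paste0(c(apt, sing), "/", ctx)]
    jac <- vapply(cl, function(x) jaccard(x$augmented, planted), numeric(1))
    expect_gte(max(jac), 0.9)
  }
})
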