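test_that("global alignment reproduces known identities and rejects empties", {
  expect_equal(global_align("ACGU", "ACGU")$percent_identity, 100)
  expect_equal(global_align("ACGU", "ACGA")$percent_identity, 75)
  expect_equal(global_align("AAAA", "CCCC")$percent_identity, 0)
  expect_error(global_align("", "ACGU"), "empty")
})

test_that("alignment scores match exhaustive enumeration on short pairs", {
  set.seed(101)
  for (r in 1:40) {
    a <- random_rna(sample(1:6, 1))
    b <- random_rna(sample(1:6, 1))
    expect_equal(global_align(a, b)$score, enum_align_score(a, b),
                 info = paste(a, b))
  }
  # and under a different scoring scheme
  cfg <- metric_config(match = 2, mismatch = -1, gap = -2)
  for (r in 1:15) {
    a <- random_rna(sample(2:6, 1))
    b <- random_rna(sample(2:6, 1))
    expect_equal(global_align(a, b, cfg)$score,
                 enum_align_score(a, b, 2, -1, -2), info = paste(a, b))
  }
})

test_that("Nussinov folding maximises pairs with the hairpin constraint", {
  expect_equal(fold_nussinov("GGGAAACCC"), "(((...)))")
  expect_equal(fold_nussinov("AAAA"), "....")
  s <- fold_nussinov("GCAAAGC")
  expect_equal(sum(strsplit(s, "")[[1]] == "("), 2)

  set.seed(202)
  for (r in 1:30) {
    seq <- random_rna(sample(5:12, 1))
    db <- fold_nussinov(seq)
    expect_equal(sum(strsplit(db, "")[[1]] == "("), enum_max_pairs(seq),
                 info = seq)
    expect_no_error(mountain_vector(db))  # well-formed structure
  }
})

test_that("mountain vectors follow the prefix-sum definition", {
  expect_equal(mountain_vector("((...))"), c(1L, 2L, 2L, 2L, 2L, 1L, 0L))
  expect_equal(mountain_vector("......."), rep(0L, 7))
  expect_error(mountain_vector("((."), "unbalanced")
  expect_error(mountain_vector("ab"), "dot-bracket")
})

test_that("mountain distance is a normalised pseudometric", {
  expect_equal(mountain_distance("((...))", "((...))"), 0)
  expect_equal(mountain_distance("((...))", ".(...)."), 3 / 7)

  # the open structure is the farthest length-9 structure from (((...)))
  all9 <- enum_structures(9)
  d <- vapply(all9, mountain_distance, numeric(1), struct_a = "(((...)))")
  expect_equal(max(d), mountain_distance("(((...)))", "........."))

  # symmetry, identity, triangle inequality on sampled triples
  set.seed(303)
  structs <- vapply(1:12, function(i) fold_nussinov(random_rna(15)),
                    character(1))
  for (r in 1:30) {
    tri <- sample(structs, 3)
    d12 <- mountain_distance(tri[1], tri[2])
    d13 <- mountain_distance(tri[1], tri[3])
    d23 <- mountain_distance(tri[2], tri[3])
    expect_equal(d12, mountain_distance(tri[2], tri[1]))
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_gte(d12, 0); expect_lte(d12, 1)
  }

  # unequal lengths reduce to the same value when one structure is repeated
  expect_equal(mountain_distance("((...))", "((...))((...))"),
               mountain_distance("((...))((...))", "((...))"))
})

test_that("combined similarity behaves at the weight and identity limits", {
  s <- "GGGCAAAAGCCCAUAUGGGAAACCC"
  expect_equal(combined_similarity(s, s), 100)
  seq_only <- metric_config(w_seq = 1, w_struct = 0)
  a <- "GGGAAACCCAU"; b <- "GGGAAACCCUA"
  expect_equal(combined_similarity(a, b, seq_only),
               global_align(a, b)$percent_identity)
  expect_equal(combined_similarity(a, b), combined_similarity(b, a))
})

test_that("pairwise matrices are consistent with the scalar metric", {
  set.seed(404)
  seqs <- stats::setNames(vapply(1:4, function(i) random_rna(30),
                                 character(1)),
                          c("s1", "s2", "s3", "s4"))
  sm <- pairwise_matrix(seqs)
  expect_equal(diag(sm$values), stats::setNames(rep(100, 4), names(seqs)))
  for (pr in list(c(1, 2), c(2, 4), c(3, 4)))
    expect_equal(sm$values[pr[1], pr[2]],
                 combined_similarity(seqs[pr[1]], seqs[pr[2]]))
  # permuting the input permutes the matrix consistently
  perm <- c(3, 1, 4, 2)
  sm2 <- pairwise_matrix(seqs[perm])
  expect_equal(sm2$values[names(seqs), names(seqs)], sm$values)
  # identical sequences give a constant-100 matrix
  same <- stats::setNames(rep(seqs[1], 3), c("a", "b", "c"))
  expect_true(all(pairwise_matrix(same)$values == 100))
})

test_that("similarity decreases with divergence between evolved relatives", {
  set.seed(505)
  params <- cohort_params()
  anc <- sample_ancestor(params)
  sim_at <- function(rate) {
    mean(vapply(1:25, function(i) {
      a <- evolve(anc$sequence, rate, anc$pairs, params)
      b <- evolve(anc$sequence, rate, anc$pairs, params)
      combined_similarity(a, b)
    }, numeric(1)))
  }
  s_low <- sim_at(0.02); s_mid <- sim_at(0.08); s_high <- sim_at(0.25)
  expect_gt(s_low, s_mid)
  expect_gt(s_mid, s_high)
})
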