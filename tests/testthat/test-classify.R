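test_that("e-value filtering keeps the boundary and preserves order", {
  hits <- rbind(hit_row("a", 1, 100, evalue = 1e-6),
                hit_row("b", 201, 300, evalue = 1e-5),
                hit_row("c", 401, 500, evalue = 1e-4))
  kept <- filter_hits(hits)
  expect_identical(kept$id, c("a", "b"))
  expect_identical(filter_hits(hits[0, ])$id, character(0))
  expect_identical(filter_hits(hits[1:2, ]), hits[1:2, ])
})

test_that("tandem calling pairs hits within the gap, greedily from 5'", {
  near <- rbind(hit_row("a", 1000, 1100), hit_row("b", 1150, 1250))
  ct <- call_tandems(near)
  expect_equal(nrow(ct$pairs), 1)
  expect_equal(ct$pairs$gap, 49)
  expect_equal(nrow(ct$singletons), 0)

  far <- rbind(hit_row("a", 1000, 1100), hit_row("b", 1252, 1352))
  ct2 <- call_tandems(far)
  expect_equal(nrow(ct2$pairs), 0)
  expect_identical(sort(ct2$singletons$id), c("a", "b"))

  # three mutually close hits: greedy pairing takes the two 5'-most
  triple <- rbind(hit_row("a", 1000, 1100), hit_row("b", 1121, 1220),
                  hit_row("c", 1241, 1340))
  ct3 <- call_tandems(triple)
  expect_equal(ct3$pairs$id_a, "a")
  expect_equal(ct3$pairs$id_b, "b")
  expect_identical(ct3$singletons$id, "c")

  # on the minus strand 5'-first means highest coordinates first
  tripm <- rbind(hit_row("a", 1000, 1100, strand = "-"),
                 hit_row("b", 1121, 1220, strand = "-"),
                 hit_row("c", 1241, 1340, strand = "-"))
  ct4 <- call_tandems(tripm)
  expect_equal(ct4$pairs$id_a, "c")
  expect_equal(ct4$pairs$id_b, "b")
  expect_identical(ct4$singletons$id, "a")

  over <- rbind(hit_row("a", 1000, 1100), hit_row("b", 1050, 1150))
  expect_error(call_tandems(over), "overlapping")
})

test_that("tandem ordering is transcriptional and input-order invariant", {
  plus <- rbind(hit_row("a", 1000, 1100), hit_row("b", 1150, 1250))
  expect_identical(order_tandem(plus)$id, c("a", "b"))
  expect_identical(order_tandem(plus[2:1, ])$id, c("a", "b"))

  minus <- rbind(hit_row("a", 1800, 1900, strand = "-"),
                 hit_row("b", 2000, 2100, strand = "-"))
  expect_identical(order_tandem(minus)$id[1], "b")

  mixed <- rbind(hit_row("a", 1000, 1100, strand = "+"),
                 hit_row("b", 1150, 1250, strand = "-"))
  expect_error(order_tandem(mixed), "mixed strands")
})

test_that("singleton typing follows ghost position in transcription direction", {
  apt <- hit_row("s", 100, 200)
  ghost <- function(start, end, strand = "+")
    data.frame(contig = "c1", start = start, end = end, strand = strand)
  expect_equal(type_singleton(apt, ghost(220, 260)), "singleton_type1")
  expect_equal(type_singleton(apt, ghost(30, 70)), "singleton_type2")
  expect_equal(type_singleton(apt, NULL), "singleton_type0")
  expect_equal(type_singleton(apt, rbind(ghost(220, 260), ghost(30, 70))),
               "singleton_type0")
  # out-of-window ghost does not count
  expect_equal(type_singleton(apt, ghost(400, 440)), "singleton_type0")
  expect_error(type_singleton(apt, ghost(150, 260)), "overlapping")

  # minus strand mirrors: ghost at lower coordinates is 3'
  aptm <- hit_row("s", 100, 200, strand = "-")
  expect_equal(type_singleton(aptm, ghost(30, 70, "-")), "singleton_type1")
  expect_equal(type_singleton(aptm, ghost(220, 260, "-")), "singleton_type2")
})

test_that("context assignment takes the nearest downstream same-strand gene", {
  apt <- hit_row("s", 500, 1000)
  gene <- function(start, end, strand = "+", product = "x")
    data.frame(contig = "c1", start = start, end = end, strand = strand,
               product = product, stringsAsFactors = FALSE)
  gcv <- gene(1200, 2000,
              product = "glycine cleavage system aminomethyltransferase")
  expect_equal(assign_context(apt, gcv), "GCV")
  expect_equal(assign_context(apt, gene(1700, 2500)), "unknown")  # 700 > 500
  expect_equal(assign_context(apt, gene(1100, 2000, strand = "-")), "unknown")
  # nearest wins when several qualify
  two <- rbind(gene(1400, 2000, product = "sodium:amino-acid symporter"), gcv)
  expect_equal(assign_context(apt, two), "GCV")
})

test_that("gene products bin by first matching keyword, falling back to Other", {
  expect_equal(bin_gene_product("sodium:amino-acid symporter"), "TP")
  expect_equal(bin_gene_product("gcvT aminomethyltransferase"), "GCV")
  expect_equal(bin_gene_product("hypothetical protein"), "Other")
  expect_equal(bin_gene_product("GLYCINE CLEAVAGE SYSTEM PROTEIN H"), "GCV")
  custom <- list(bin1 = "protein")
  expect_equal(bin_gene_product("hypothetical protein", custom), "bin1")
})

test_that("every filtered hit receives exactly one role", {
  co <- generate_cohort(cohort_params(seed = 11, n_tandem_per_context = 5,
                                      n_singleton_per_context = 3))
  rec <- classify_aptamers(co$hits, co$ghost_hits, co$annotations,
                           co$metadata)
  expect_equal(nrow(rec), nrow(filter_hits(co$hits)))
  expect_false(any(is.na(rec$role)))
  # tandem partners are symmetric and share a riboswitch id
  tan <- rec[grepl("^tandem", rec$role), ]
  expect_identical(rec$partner_id[match(tan$partner_id, rec$id)], tan$id)
  expect_identical(rec$riboswitch_id[match(tan$partner_id, rec$id)],
                   tan$riboswitch_id)
  expect_true(all(is.na(rec$partner_id[grepl("singleton", rec$role)])))
})

test_that("roles and contexts are invariant under coordinate-frame reflection", {
  co <- generate_cohort(cohort_params(seed = 12, n_tandem_per_context = 4,
                                      n_singleton_per_context = 3))
  rec <- classify_aptamers(co$hits, co$ghost_hits, co$annotations)
  M <- 10000L  # reflect every interval within [1, M] and flip strands
  flip <- function(df) {
    s <- M - df$end + 1L
    e <- M - df$start + 1L
    df$start <- s; df$end <- e
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  rec2 <- classify_aptamers(flip(co$hits), flip(co$ghost_hits),
                            flip(co$annotations))
  expect_identical(rec2$role[match(rec$id, rec2$id)], rec$role)
  expect_identical(rec2$context[match(rec$id, rec2$id)], rec$context)
})

test_that("species-level deduplication collapses identical riboswitches only", {
  base <- rbind(hit_row("a1", 1000, 1100), hit_row("a2", 1121, 1220))
  rec <- classify_aptamers(base)
  mk <- function(rec, suffix, genus, species, strain, seqs) {
    r <- rec
    r$id <- paste0(r$id, suffix)
    r$partner_id <- ifelse(is.na(r$partner_id), NA,
                           paste0(r$partner_id, suffix))
    r$riboswitch_id <- paste0(r$riboswitch_id, suffix)
    r$contig <- paste0(r$contig, suffix)
    r$organism_genus <- genus; r$organism_species <- species
    r$strain <- strain
    names(seqs) <- r$id
    list(rec = r, seqs = seqs)
  }
  s <- c("ACGUACGUAC", "GGGAAACCCU")
  x1 <- mk(rec, "_x1", "Bacillus", "subtilis", "A", s)
  x2 <- mk(rec, "_x2", "Bacillus", "subtilis", "B", s)          # same species
  x3 <- mk(rec, "_x3", "Bacillus", "cereus", "A", s)            # other species
  x4 <- mk(rec, "_x4", "Bacillus", "subtilis", "A",
           c("ACGUACGUAC", "GGGAAACCCA"))                       # other sequence
  all_rec <- rbind(x1$rec, x2$rec, x3$rec, x4$rec)
  all_seq <- c(x1$seqs, x2$seqs, x3$seqs, x4$seqs)
  kept <- dedup_by_species(all_rec, all_seq)
  kept_units <- unique(kept$riboswitch_id)
  expect_equal(length(kept_units), 3)  # x1/x2 collapsed; x3, x4 kept
  expect_true(any(grepl("_x3$", kept_units)))
  expect_true(any(grepl("_x4$", kept_units)))
  expect_equal(sum(grepl("_x[12]$", kept_units)), 1)
})
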