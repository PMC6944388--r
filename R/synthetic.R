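#' Parameters of the synthetic aptamer cohort generator
#'
#' The generator emulates the evolutionary scenario the network analysis is
#' designed to detect: in each genomic context a tandem ancestor (two
#' independently sampled three-stem aptamers) gives rise to descendant
#' riboswitches on a star phylogeny.  One aptamer of the pair -- which one
#' depends on the context -- evolves slowly (`rate_conserved`), the other
#' quickly (`rate_degraded`); singleton descendants carry the conserved
#' aptamer plus the degraded aptamer truncated to its P1 stem (the ghost),
#' 3' of the aptamer when aptamer-2 degrades (type-1 geometry) and 5' when
#' aptamer-1 degrades (type-2).
#'
#' @param n_tandem_per_context tandem descendants per context.
#' @param n_singleton_per_context singleton descendants per context.
#' @param aptamer_length aptamer length in nt (>= 70; three designed stems).
#' @param ghost_length ghost stem length in nt.
#' @param rate_conserved,rate_degraded per-site substitution probabilities on
#'   the conserved / degraded branch; `rate_conserved <= rate_degraded`
#'   (equality gives the null model with no conservation asymmetry).
#' @param conserved_map named list or vector: context -> `"apt1"` or
#'   `"apt2"`, naming the conserved aptamer of a tandem in that context.
#' @param pairing_preservation probability that a substitution hitting a
#'   paired site is accompanied by the compensatory change at its partner.
#' @param noise_fraction fraction of singletons whose ghost is placed on the
#'   wrong side, reintroducing label noise into the context-type
#'   association (the idealised default is 0).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list of class `"cohort_params"`.
#' @export
cohort_params <- function(n_tandem_per_context = 30L,
                          n_singleton_per_context = 15L,
                          aptamer_length = 100L,
                          ghost_length = 30L,
                          rate_conserved = 0.03,
                          rate_degraded = 0.15,
                          conserved_map = c(GCV = "apt1", TP = "apt2"),
                          pairing_preservation = 0.7,
                          noise_fraction = 0,
                          seed = 1L) {
  stopifnot(rate_conserved >= 0, rate_degraded >= 0,
            rate_conserved <= 0.75, rate_degraded <= 0.75,
            rate_conserved <= rate_degraded,
            aptamer_length >= 70, ghost_length >= 20,
            ghost_length <= aptamer_length,
            pairing_preservation >= 0, pairing_preservation <= 1,
            noise_fraction >= 0, noise_fraction <= 1,
            all(unlist(conserved_map) %in% c("apt1", "apt2")))
  structure(list(n_tandem_per_context = as.integer(n_tandem_per_context),
                 n_singleton_per_context = as.integer(n_singleton_per_context),
                 aptamer_length = as.integer(aptamer_length),
                 ghost_length = as.integer(ghost_length),
                 rate_conserved = rate_conserved,
                 rate_degraded = rate_degraded,
                 conserved_map = conserved_map,
                 pairing_preservation = pairing_preservation,
                 noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

rna_bases <- c("A", "C", "G", "U")
wc_complement <- c(A = "U", U = "A", G = "C", C = "G")

#' Sample a structured ancestral aptamer
#'
#' Designs a length-L sequence with three helices mimicking the glycine
#' aptamer architecture: a closing P1 stem (8 bp, terminal arms) enclosing
#' two 8-bp hairpins (P2, P3) with 6-nt loops, joined by unpaired linkers.
#' Paired positions are Watson-Crick complementary by construction; all
#' remaining positions are uniform random bases.  Uses R's global RNG.
#'
#' @param params a [cohort_params()].
#' @return list with `sequence`, `pairs` (2-column matrix of paired
#'   positions) and `structure` (dot-bracket template).
#' @export
sample_ancestor <- function(params = cohort_params()) {
  L <- params$aptamer_length
  stem <- 8L; loop <- 6L
  linker_total <- L - (6L * stem + 2L * loop)
  j1 <- linker_total %/% 3L
  j2 <- linker_total %/% 3L
  j3 <- linker_total - j1 - j2
  pos <- 8L  # end of P1 5' arm
  p1 <- cbind(1:8, L - (1:8) + 1L)
  p2a <- pos + j1 + (1:stem); pos2 <- pos + j1 + stem + loop
  p2 <- cbind(p2a, pos2 + (stem:1))
  pos3 <- pos2 + stem
  p3a <- pos3 + j2 + (1:stem); pos4 <- pos3 + j2 + stem + loop
  p3 <- cbind(p3a, pos4 + (stem:1))
  pairs <- rbind(p1, p2, p3)
  seqv <- sample(rna_bases, L, replace = TRUE)
  left <- sample(rna_bases, nrow(pairs), replace = TRUE)
  seqv[pairs[, 1]] <- left
  seqv[pairs[, 2]] <- wc_complement[left]
  db <- rep(".", L)
  db[pairs[, 1]] <- "("
  db[pairs[, 2]] <- ")"
  list(sequence = paste(seqv, collapse = ""), pairs = pairs,
       structure = paste(db, collapse = ""))
}

#' Evolve a sequence along one branch of the star phylogeny
#'
#' Single-round uniform substitution model: each site mutates with
#' probability `rate` to one of the three other bases uniformly.  When a
#' mutation hits a site paired in the structure template, the complementary
#' substitution is applied to its partner with probability
#' `pairing_preservation` (compensatory change).  Uses R's global RNG.
#'
#' @param sequence RNA string.
#' @param rate per-site substitution probability in `[0, 0.75]`.
#' @param pairs 2-column matrix of paired positions (the structure
#'   template), or NULL for no compensation.
#' @param params a [cohort_params()] (supplies `pairing_preservation`).
#' @return the evolved RNA string.
#' @export
evolve <- function(sequence, rate, pairs = NULL, params = cohort_params()) {
  if (rate < 0 || rate > 0.75)
    stop("substitution rate must lie in [0, 0.75]")
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  partner <- rep(NA_integer_, length(s))
  if (!is.null(pairs)) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) {
    new <- sample(setdiff(rna_bases, s[i]), 1)
    s[i] <- new
    if (!is.na(partner[i]) && stats::runif(1) < params$pairing_preservation)
      s[partner[i]] <- wc_complement[[new]]
  }
  paste(s, collapse = "")
}

truncate_to_ghost <- function(sequence, params) {
  L <- nchar(sequence)
  arm <- 8L
  interior <- params$ghost_length - 2L * arm
  paste0(substr(sequence, 1, arm + interior),
         substr(sequence, L - arm + 1L, L))
}

#' Generate a synthetic aptamer cohort with ground truth
#'
#' Emits, per context in `conserved_map`: `n_tandem_per_context` tandem
#' riboswitches and `n_singleton_per_context` singletons descending from one
#' tandem ancestor, laid out on per-riboswitch contigs with alternating
#' strands, each with a context-consistent downstream gene annotation, so
#' the classification module can be exercised end to end.  All randomness
#' derives from `params$seed`.
#'
#' @param params a [cohort_params()].
#' @return list with elements `sequences` (aptamer sequence set),
#'   `ghost_sequences`, `hits` (aptamer hit table with e-values),
#'   `ghost_hits`, `annotations` (gene table), `metadata`, `truth`
#'   (data.frame: id, riboswitch, context, role, rate, ancestor) and
#'   `params`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  set.seed(params$seed)
  L <- params$aptamer_length
  gap <- 20L  # intervening nt between tandem aptamers / aptamer and ghost
  seqs <- character(); ghosts <- character()
  hits <- list(); ghost_hits <- list(); ann <- list()
  meta <- list(); truth <- list()
  add_hit <- function(id, contig, start, end, strand) {
    data.frame(id = id, contig = contig, start = start, end = end,
               strand = strand,
               evalue = 10^stats::runif(1, -12, -8),
               stringsAsFactors = FALSE)
  }
  gene_product <- c(GCV = "glycine cleavage system aminomethyltransferase",
                    TP = "sodium:amino-acid symporter")
  rs_index <- 0L
  for (ctx in names(params$conserved_map)) {
    conserved <- params$conserved_map[[ctx]]
    anc1 <- sample_ancestor(params)
    anc2 <- sample_ancestor(params)
    rate1 <- if (conserved == "apt1") params$rate_conserved else
      params$rate_degraded
    rate2 <- if (conserved == "apt2") params$rate_conserved else
      params$rate_degraded
    for (i in seq_len(params$n_tandem_per_context)) {
      rs_index <- rs_index + 1L
      rsname <- paste0(ctx, "_t", i)
      contig <- paste0("ctg_", rsname)
      strand <- if (rs_index %% 2L == 1L) "+" else "-"
      a1 <- evolve(anc1$sequence, rate1, anc1$pairs, params)
      a2 <- evolve(anc2$sequence, rate2, anc2$pairs, params)
      id1 <- paste0(rsname, "_a1"); id2 <- paste0(rsname, "_a2")
      seqs[id1] <- a1; seqs[id2] <- a2
      # transcription-ordered elements: apt1, gap, apt2, 100 nt, gene
      coords <- layout_elements(c(L, L), gap, strand)
      hits[[length(hits) + 1L]] <- rbind(
        add_hit(id1, contig, coords$start[1], coords$end[1], strand),
        add_hit(id2, contig, coords$start[2], coords$end[2], strand))
      ann[[length(ann) + 1L]] <- gene_row(coords, strand, contig,
                                          gene_product[[ctx]])
      meta[[length(meta) + 1L]] <- meta_rows(c(id1, id2), rsname, contig,
                                             coords, strand)
      truth[[length(truth) + 1L]] <- data.frame(
        id = c(id1, id2), riboswitch = rsname, context = ctx,
        role = c("tandem_apt1", "tandem_apt2"), rate = c(rate1, rate2),
        ancestor = c("anc1", "anc2"), stringsAsFactors = FALSE)
    }
    for (i in seq_len(params$n_singleton_per_context)) {
      rs_index <- rs_index + 1L
      rsname <- paste0(ctx, "_s", i)
      contig <- paste0("ctg_", rsname)
      strand <- if (rs_index %% 2L == 1L) "+" else "-"
      apt_first <- conserved == "apt1"  # conserved aptamer 5' of the ghost?
      if (stats::runif(1) < params$noise_fraction) apt_first <- !apt_first
      anc <- if (conserved == "apt1") anc1 else anc2
      danc <- if (conserved == "apt1") anc2 else anc1
      apt <- evolve(anc$sequence, params$rate_conserved, anc$pairs, params)
      ghost <- truncate_to_ghost(
        evolve(danc$sequence, params$rate_degraded, danc$pairs, params),
        params)
      id <- paste0(rsname, "_apt"); gid <- paste0(rsname, "_ghost")
      seqs[id] <- apt; ghosts[gid] <- ghost
      lens <- if (apt_first) c(L, params$ghost_length) else
        c(params$ghost_length, L)
      coords <- layout_elements(lens, gap, strand)
      ai <- if (apt_first) 1L else 2L; gi <- 3L - ai
      hits[[length(hits) + 1L]] <-
        add_hit(id, contig, coords$start[ai], coords$end[ai], strand)
      ghost_hits[[length(ghost_hits) + 1L]] <- data.frame(
        id = gid, contig = contig, start = coords$start[gi],
        end = coords$end[gi], strand = strand, stringsAsFactors = FALSE)
      ann[[length(ann) + 1L]] <- gene_row(coords, strand, contig,
                                          gene_product[[ctx]])
      meta[[length(meta) + 1L]] <- meta_rows(id, rsname, contig,
        list(start = coords$start[ai], end = coords$end[ai]), strand)
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, riboswitch = rsname, context = ctx,
        role = if (apt_first) "singleton_type1" else "singleton_type2",
        rate = params$rate_conserved, ancestor = conserved,
        stringsAsFactors = FALSE)
    }
  }
  list(sequences = as_sequence_set(seqs),
       ghost_sequences = if (length(ghosts)) as_sequence_set(ghosts) else
         structure(character(), class = "sequence_set"),
       hits = do.call(rbind, hits),
       ghost_hits = if (length(ghost_hits)) do.call(rbind, ghost_hits) else
         NULL,
       annotations = do.call(rbind, ann),
       metadata = do.call(rbind, meta),
       truth = do.call(rbind, truth),
       params = params)
}

# genome placement of transcription-ordered elements of the given lengths,
# separated by `gap` intervening nt, starting at offset 1000; the regulated
# gene starts 100 nt after the last element (all in transcription direction)
layout_elements <- function(lengths, gap, strand) {
  n <- length(lengths)
  starts_t <- integer(n)  # transcription-direction offsets
  off <- 1001L
  for (i in seq_len(n)) {
    starts_t[i] <- off
    off <- off + lengths[i] + gap
  }
  gene_start_t <- starts_t[n] + lengths[n] - 1L + 100L + 1L
  gene_len <- 900L
  if (strand == "+") {
    list(start = starts_t, end = starts_t + lengths - 1L,
         gene_start = gene_start_t, gene_end = gene_start_t + gene_len - 1L)
  } else {
    span <- gene_start_t + gene_len  # mirror within [1, span]
    flip <- function(p) span - p + 1L
    list(start = flip(starts_t + lengths - 1L), end = flip(starts_t),
         gene_start = flip(gene_start_t + gene_len - 1L),
         gene_end = flip(gene_start_t))
  }
}

gene_row <- function(coords, strand, contig, product) {
  data.frame(contig = contig, start = coords$gene_start,
             end = coords$gene_end, strand = strand, product = product,
             stringsAsFactors = FALSE)
}

meta_rows <- function(ids, rsname, contig, coords, strand) {
  data.frame(id = ids, organism_genus = "Synthetica",
             organism_species = rsname, strain = "s1", contig = contig,
             start = coords$start, end = coords$end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Role-and-context group labels from a cohort truth table
#'
#' Maps each aptamer id to the group label used in network analyses:
#' `"apt1/<context>"`, `"apt2/<context>"`, `"sing1/<context>"` or
#' `"sing2/<context>"`.
#'
#' @param truth the `truth` element of [generate_cohort()].
#' @return named character vector id -> group.
#' @export
truth_groups <- function(truth) {
  short <- c(tandem_apt1 = "apt1", tandem_apt2 = "apt2",
             singleton_type1 = "sing1", singleton_type2 = "sing2",
             singleton_type0 = "sing0")
  stats::setNames(paste0(short[truth$role], "/", truth$context), truth$id)
}
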