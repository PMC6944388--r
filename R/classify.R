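#' Configuration for architecture and context classification
#'
#' Defaults follow the conventions used for glycine riboswitch annotation:
#' two aptamer hits separated by at most 100 intervening nucleotides form a
#' tandem riboswitch, the regulated gene is the nearest same-strand gene
#' starting within 500 nt downstream of the aptamer, and hits are kept when
#' their e-value is at most 1e-5 (boundary inclusive).
#'
#' @param max_tandem_gap maximum intervening nucleotides between the two
#'   aptamers of a tandem (gap = next start - previous end - 1).
#' @param max_context_dist maximum distance (nt, transcription direction,
#'   aptamer 3' end to gene 5' start) for context assignment.
#' @param evalue_threshold keep hits with `evalue <= evalue_threshold`.
#' @param context_keyword_map ordered named list: bin -> character vector of
#'   case-insensitive substrings matched against gene product descriptions.
#'   First matching bin wins; no match falls through to `"Other"`.
#' @return list of class `"classify_config"`.
#' @export
classify_config <- function(max_tandem_gap = 100L,
                            max_context_dist = 500L,
                            evalue_threshold = 1e-5,
                            context_keyword_map = default_context_keywords()) {
  stopifnot(max_tandem_gap > 0, max_context_dist > 0, evalue_threshold > 0)
  structure(list(max_tandem_gap = as.integer(max_tandem_gap),
                 max_context_dist = as.integer(max_context_dist),
                 evalue_threshold = evalue_threshold,
                 context_keyword_map = context_keyword_map),
            class = "classify_config")
}

#' Default gene-product keyword map for genomic-context binning
#'
#' Bins: `GCV` (glycine cleavage system), `TP` (transport proteins),
#' `Gly_Met` (other glycine metabolism).  Entirely user-overridable; the
#' vocabulary here covers the product strings RefSeq uses for the gene
#' families most often found downstream of glycine riboswitches.
#'
#' @return named list of keyword vectors, in match priority order.
#' @export
default_context_keywords <- function() {
  list(
    GCV = c("glycine cleavage", "gcvt", "gcvp", "gcvh",
            "aminomethyltransferase", "glycine dehydrogenase",
            "glycine decarboxylase"),
    TP = c("symporter", "transporter", "transport", "permease", "antiporter"),
    Gly_Met = c("hydroxymethyltransferase", "glycine reductase",
                "sarcosine", "glycine betaine", "serine dehydratase")
  )
}

#' Filter aptamer hits by e-value
#'
#' @param hits data.frame with at least columns `id` and `evalue`.
#' @param config a [classify_config()].
#' @return the passing rows, input order preserved.
#' @export
filter_hits <- function(hits, config = classify_config()) {
  hits[hits$evalue <= config$evalue_threshold, , drop = FALSE]
}

hit_cols <- c("id", "contig", "start", "end", "strand")

check_hits <- function(hits) {
  missing <- setdiff(hit_cols, names(hits))
  if (length(missing))
    stop("hit table is missing column(s): ", paste(missing, collapse = ", "))
  validate_coordinates(hits, "hits")
  if (anyDuplicated(hits$id))
    stop("duplicate hit id(s): ",
         paste(unique(hits$id[duplicated(hits$id)]), collapse = ", "))
  invisible(hits)
}

#' Pair adjacent hits into tandem riboswitches
#'
#' Hits are grouped by contig and strand and scanned in transcription
#' direction (5' to 3'); two neighbouring hits whose intervening gap
#' (`next start - previous end - 1` in genome coordinates) is at most
#' `max_tandem_gap` are paired greedily from the 5' end.  Each hit joins at
#' most one pair; leftover hits are singleton candidates.  Overlapping hits
#' on the same contig and strand are an error (ambiguous architecture).
#'
#' @param hits data.frame of aptamer hits (id, contig, start, end, strand).
#' @param config a [classify_config()].
#' @return list with elements `pairs` (data.frame id_a, id_b in transcription
#'   order, gap, contig, strand) and `singletons` (unpaired hit rows).
#' @export
call_tandems <- function(hits, config = classify_config()) {
  check_hits(hits)
  pairs <- list()
  single_ids <- character()
  for (key in unique(paste(hits$contig, hits$strand))) {
    h <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    if (nrow(h) > 1) {
      ov <- which(h$start[-1] <= h$end[-nrow(h)])
      if (length(ov))
        stop("overlapping hits on ", h$contig[1], h$strand[1], ": ",
             h$id[ov[1]], " and ", h$id[ov[1] + 1])
    }
    # transcription direction: ascending coordinates on '+', descending on '-'
    if (h$strand[1] == "-") h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
    i <- 1L
    while (i <= nrow(h)) {
      if (i < nrow(h)) {
        gap <- if (h$strand[1] == "+") h$start[i + 1] - h$end[i] - 1L
               else h$start[i] - h$end[i + 1] - 1L
        if (gap <= config$max_tandem_gap) {
          pairs[[length(pairs) + 1L]] <-
            data.frame(id_a = h$id[i], id_b = h$id[i + 1], gap = gap,
                       contig = h$contig[1], strand = h$strand[1],
                       stringsAsFactors = FALSE)
          i <- i + 2L
          next
        }
      }
      single_ids <- c(single_ids, h$id[i])
      i <- i + 1L
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id_a = character(), id_b = character(), gap = integer(),
               contig = character(), strand = character(),
               stringsAsFactors = FALSE)
  list(pairs = pairs,
       singletons = hits[hits$id %in% single_ids, , drop = FALSE])
}

#' Order the two hits of a tandem pair transcriptionally
#'
#' Aptamer-1 is the 5' aptamer in transcription direction: the lower-start
#' hit on the plus strand, the higher-start hit on the minus strand.
#'
#' @param pair data.frame of exactly two hit rows on one strand.
#' @return the same rows reordered so row 1 is aptamer-1.
#' @export
order_tandem <- function(pair) {
  if (nrow(pair) != 2) stop("a tandem pair must contain exactly two hits")
  if (length(unique(pair$strand)) != 1)
    stop("tandem pair spans mixed strands")
  decreasing <- pair$strand[1] == "-"
  pair[order(pair$start, decreasing = decreasing), , drop = FALSE]
}

#' Type a singleton aptamer by ghost-aptamer position
#'
#' Ghost-aptamer intervals (detected externally, e.g. by covariance-model
#' scans, or emitted by the synthetic generator) are matched to the aptamer
#' by contig and strand.  A ghost strictly 3' of the aptamer in transcription
#' direction, within `max_tandem_gap` intervening nucleotides, makes the
#' singleton type-1; strictly 5', type-2; no ghost in range (or ghosts on
#' both sides) leaves it type-0.  A ghost overlapping the aptamer is an
#' error.
#'
#' @param record one hit row (id, contig, start, end, strand).
#' @param ghost_hits data.frame of ghost intervals (contig, start, end,
#'   strand); may be empty.
#' @param config a [classify_config()].
#' @return one of `"singleton_type1"`, `"singleton_type2"`,
#'   `"singleton_type0"`.
#' @export
type_singleton <- function(record, ghost_hits, config = classify_config()) {
  if (is.null(ghost_hits) || nrow(ghost_hits) == 0) return("singleton_type0")
  g <- ghost_hits[ghost_hits$contig == record$contig &
                  ghost_hits$strand == record$strand, , drop = FALSE]
  if (nrow(g) == 0) return("singleton_type0")
  ov <- g$start <= record$end & g$end >= record$start
  if (any(ov))
    stop("ghost hit overlapping aptamer ", record$id)
  if (record$strand == "+") {
    gap3 <- g$start - record$end - 1L   # ghost right of aptamer
    gap5 <- record$start - g$end - 1L   # ghost left of aptamer
  } else {
    gap3 <- record$start - g$end - 1L
    gap5 <- g$start - record$end - 1L
  }
  has3 <- any(gap3 >= 0 & gap3 <= config$max_tandem_gap)
  has5 <- any(gap5 >= 0 & gap5 <= config$max_tandem_gap)
  if (has3 && !has5) "singleton_type1"
  else if (has5 && !has3) "singleton_type2"
  else "singleton_type0"
}

#' Bin a gene product description into a genomic-context label
#'
#' First bin whose keyword list matches the product as a case-insensitive
#' substring wins; unmatched products fall through to `"Other"`.
#'
#' @param product free-text gene product description.
#' @param keyword_map ordered named list of keyword vectors.
#' @return bin name.
#' @export
bin_gene_product <- function(product,
                             keyword_map = default_context_keywords()) {
  p <- tolower(product)
  for (bin in names(keyword_map)) {
    if (any(vapply(tolower(keyword_map[[bin]]),
                   function(k) grepl(k, p, fixed = TRUE), logical(1))))
      return(bin)
  }
  "Other"
}

#' Assign genomic context from the nearest downstream gene
#'
#' Among genes on the same contig and strand whose 5' start lies strictly
#' downstream (transcription direction) of the aptamer 3' end and within
#' `max_context_dist` nucleotides, the nearest one is taken and its product
#' binned with [bin_gene_product()].  No such gene gives `"unknown"`.
#'
#' @param record one hit row.
#' @param annotations gene annotation data.frame
#'   (see [read_gene_annotations()]).
#' @param config a [classify_config()].
#' @return context label.
#' @export
assign_context <- function(record, annotations, config = classify_config()) {
  if (is.null(annotations) || nrow(annotations) == 0) return("unknown")
  g <- annotations[annotations$contig == record$contig &
                   annotations$strand == record$strand, , drop = FALSE]
  if (nrow(g) == 0) return("unknown")
  dist <- if (record$strand == "+") g$start - record$end
          else record$start - g$end
  ok <- dist >= 1 & dist <= config$max_context_dist
  if (!any(ok)) return("unknown")
  nearest <- g[ok, , drop = FALSE][which.min(dist[ok]), ]
  bin_gene_product(nearest$product, config$context_keyword_map)
}

#' Classify filtered aptamer hits into architecture roles and contexts
#'
#' Driver composing [filter_hits()], [call_tandems()], [order_tandem()],
#' [type_singleton()] and [assign_context()].  Every filtered hit ends with
#' exactly one role: `tandem_apt1`/`tandem_apt2` (paired, sharing a
#' `riboswitch_id` and symmetric `partner_id`) or one of the three singleton
#' types.
#'
#' @param hits hit table (id, contig, start, end, strand, evalue).
#' @param ghost_hits optional ghost-aptamer intervals for singleton typing.
#' @param annotations optional gene annotations for context assignment.
#' @param metadata optional metadata table; organism columns are joined by id.
#' @param config a [classify_config()].
#' @return data.frame of aptamer records with columns role, partner_id,
#'   riboswitch_id and context added to the hit columns.
#' @export
classify_aptamers <- function(hits, ghost_hits = NULL, annotations = NULL,
                              metadata = NULL, config = classify_config()) {
  hits <- filter_hits(hits, config)
  check_hits(hits)
  ct <- call_tandems(hits, config)
  rec <- hits
  rec$role <- NA_character_
  rec$partner_id <- NA_character_
  rec$riboswitch_id <- NA_character_
  rownames(rec) <- rec$id
  if (nrow(ct$pairs)) {
    for (r in seq_len(nrow(ct$pairs))) {
      a <- ct$pairs$id_a[r]; b <- ct$pairs$id_b[r]
      rsid <- paste0("rs_", a)
      rec[a, c("role", "partner_id", "riboswitch_id")] <-
        c("tandem_apt1", b, rsid)
      rec[b, c("role", "partner_id", "riboswitch_id")] <-
        c("tandem_apt2", a, rsid)
    }
  }
  for (id in ct$singletons$id) {
    rec[id, "role"] <- type_singleton(rec[id, ], ghost_hits, config)
    rec[id, "riboswitch_id"] <- paste0("rs_", id)
  }
  rec$context <- vapply(seq_len(nrow(rec)), function(i)
    assign_context(rec[i, ], annotations, config), character(1))
  if (!is.null(metadata)) {
    org <- metadata[match(rec$id, metadata$id),
                    c("organism_genus", "organism_species", "strain")]
    rec <- cbind(rec, org)
  }
  rownames(rec) <- NULL
  rec
}

#' Deduplicate records by species and sequence content
#'
#' Identical aptamers (for tandems: the concatenated aptamer-1 + aptamer-2
#' sequence of the riboswitch) from different strains of the same species
#' collapse to one representative -- the first riboswitch by (contig, start)
#' sort.  Identical sequences from different species, and different sequences
#' from one strain, are all kept.
#'
#' @param records classified records with organism columns populated.
#' @param sequences sequence set covering every record id.
#' @return the surviving record rows.
#' @export
dedup_by_species <- function(records, sequences) {
  need <- c("organism_genus", "organism_species")
  if (!all(need %in% names(records)))
    stop("dedup_by_species needs organism columns; join metadata first")
  miss <- setdiff(records$id, names(sequences))
  if (length(miss))
    stop("no sequence for record id(s): ", paste(miss, collapse = ", "))
  units <- split(records, records$riboswitch_id)
  keys <- vapply(units, function(u) {
    u <- u[order(match(u$role, c("tandem_apt1", "tandem_apt2"))), ]
    paste(u$organism_genus[1], u$organism_species[1],
          paste(sequences[u$id], collapse = "|"), sep = "\r")
  }, character(1))
  first_pos <- vapply(units, function(u)
    paste(u$contig[1], formatC(min(u$start), width = 12, flag = "0")),
    character(1))
  keep <- unlist(lapply(split(names(units), keys), function(ids)
    ids[order(first_pos[ids])][1]), use.names = FALSE)
  out <- records[records$riboswitch_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
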