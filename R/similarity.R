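#' Parameters of the built-in sequence+structure similarity metric
#'
#' The built-in metric combines global-alignment percent identity (match +1,
#' mismatch 0, gap -1 by default) with a mountain-function distance between
#' Nussinov-predicted secondary structures, with equal weights.  Externally
#' computed matrices can always be substituted via [read_score_matrix()];
#' this metric exists so the pipeline is self-contained.
#'
#' @param match,mismatch,gap alignment scoring parameters.
#' @param min_loop minimum unpaired-or-nested positions enclosed by a base
#'   pair (hairpin constraint), in nucleotides.
#' @param w_seq,w_struct non-negative weights of the sequence and structure
#'   components; must sum to 1.
#' @return list of class `"metric_config"`.
#' @export
metric_config <- function(match = 1, mismatch = 0, gap = -1, min_loop = 3L,
                          w_seq = 0.5, w_struct = 0.5) {
  stopifnot(w_seq >= 0, w_struct >= 0, abs(w_seq + w_struct - 1) < 1e-12,
            min_loop >= 0)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 min_loop = as.integer(min_loop),
                 w_seq = w_seq, w_struct = w_struct),
            class = "metric_config")
}

#' Optimal global alignment of two RNA sequences
#'
#' Needleman-Wunsch dynamic programming under a linear gap penalty, with a
#' deterministic traceback (ties resolved diagonal, then up, then left).
#' Percent identity is identical aligned columns over total alignment length.
#'
#' @param seq_a,seq_b non-empty RNA strings.
#' @param config a [metric_config()].
#' @return list with `score`, `aligned_a`, `aligned_b`, `percent_identity`.
#' @export
global_align <- function(seq_a, seq_b, config = metric_config()) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("cannot align an empty sequence")
  nw_align_cpp(seq_a, seq_b, config$match, config$mismatch, config$gap)
}

#' Predict a secondary structure by base-pair maximisation
#'
#' Nussinov-style dynamic programming maximising the number of nested base
#' pairs over `{AU, UA, GC, CG, GU, UG}`, subject to the hairpin constraint
#' `min_loop`.  The traceback tie-break is fixed (prefer a position unpaired,
#' then the smallest admissible partner), so the returned structure is a
#' deterministic function of the sequence.
#'
#' @param seq RNA string.
#' @param config a [metric_config()].
#' @return dot-bracket string of the same length as `seq`.
#' @export
fold_nussinov <- function(seq, config = metric_config()) {
  seq <- unname(chartr("T", "U", toupper(seq)))
  if (grepl("[^ACGU]", seq)) stop("fold_nussinov: sequence must be RNA (ACGU)")
  nussinov_cpp(seq, config$min_loop)
}

#' Mountain representation of a dot-bracket structure
#'
#' `values[i]` is the number of base pairs enclosing position `i`: the count
#' of `(` minus the count of `)` among positions `1..i`.  A balanced
#' structure ends at height 0.
#'
#' @param structure dot-bracket string.
#' @return integer vector of per-position heights.
#' @export
mountain_vector <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("structure must be a dot-bracket string over '(', ')', '.'")
  m <- cumsum((ch == "(") - (ch == ")"))
  if (length(m) && (m[length(m)] != 0 || any(m < 0)))
    stop("unbalanced dot-bracket structure")
  as.integer(m)
}

#' Normalised mountain distance between two secondary structures
#'
#' For equal lengths: the mean absolute difference of the two mountain
#' vectors, divided by the larger peak height of either (or 1 when both are
#' unpaired), so the result lies in `[0, 1]` and is comparable across
#' aptamers of different sizes.  For unequal lengths both mountains are
#' mapped onto `[0, 1]` as piecewise-constant step functions of relative
#' position and the same normalised L1 distance is integrated exactly.
#'
#' @param struct_a,struct_b dot-bracket strings.
#' @return distance in `[0, 1]`.
#' @export
mountain_distance <- function(struct_a, struct_b) {
  ma <- mountain_vector(struct_a)
  mb <- mountain_vector(struct_b)
  peak <- max(ma, mb, 1L)
  la <- length(ma); lb <- length(mb)
  if (la == lb) {
    return(mean(abs(ma - mb)) / peak)
  }
  bp <- sort(unique(c(seq_len(la) / la, seq_len(lb) / lb)))
  left <- c(0, bp[-length(bp)])
  mid <- (left + bp) / 2
  fa <- ma[ceiling(mid * la)]
  fb <- mb[ceiling(mid * lb)]
  sum((bp - left) * abs(fa - fb)) / peak
}

#' Combined sequence+structure similarity of two aptamers
#'
#' `S = 100 * (w_seq * pid/100 + w_struct * (1 - mountain_distance))`, where
#' `pid` is the global-alignment percent identity and the mountain distance
#' is computed between the Nussinov folds of the two sequences.  Identical
#' sequences score 100; the score is symmetric in its arguments.
#'
#' @param seq_a,seq_b RNA strings.
#' @param config a [metric_config()].
#' @return similarity in `[0, 100]`.
#' @export
combined_similarity <- function(seq_a, seq_b, config = metric_config()) {
  pid <- global_align(seq_a, seq_b, config)$percent_identity
  d <- mountain_distance(fold_nussinov(seq_a, config),
                         fold_nussinov(seq_b, config))
  100 * (config$w_seq * pid / 100 + config$w_struct * (1 - d))
}

#' Pairwise similarity matrix over a sequence set
#'
#' Scores every unordered pair with the built-in combined metric.  Each
#' sequence is folded once and the fold reused across its pairs.  The
#' diagonal is the self-similarity, 100.
#'
#' @param sequences sequence set (named character vector, >= 2 entries).
#' @param config a [metric_config()].
#' @return a [similarity_matrix()] with `metric_name = "combined"` and
#'   `higher_is_similar = TRUE`.
#' @export
pairwise_matrix <- function(sequences, config = metric_config()) {
  sequences <- as_sequence_set(sequences)
  n <- length(sequences)
  if (n < 2) stop("pairwise_matrix needs at least 2 sequences")
  ids <- names(sequences)
  pid <- pid_matrix_cpp(unname(sequences), config$match, config$mismatch,
                        config$gap)
  folds <- vapply(sequences, fold_nussinov, character(1), config = config)
  mountains <- lapply(folds, mountain_vector)
  lens <- lengths(mountains)
  peaks <- vapply(mountains, function(m) max(m, 1L), integer(1))
  sdist <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sdist[i, j] <- sdist[j, i] <-
        mountain_distance_vec(mountains[[i]], mountains[[j]],
                              max(peaks[i], peaks[j]))
    }
  }
  vals <- 100 * (config$w_seq * pid / 100 + config$w_struct * (1 - sdist))
  dimnames(vals) <- list(ids, ids)
  similarity_matrix(vals, metric_name = "combined", higher_is_similar = TRUE)
}

# mountain_distance on precomputed vectors with a precomputed peak
mountain_distance_vec <- function(ma, mb, peak) {
  la <- length(ma); lb <- length(mb)
  if (la == lb) return(mean(abs(ma - mb)) / peak)
  bp <- sort(unique(c(seq_len(la) / la, seq_len(lb) / lb)))
  left <- c(0, bp[-length(bp)])
  mid <- (left + bp) / 2
  sum((bp - left) * abs(ma[ceiling(mid * la)] - mb[ceiling(mid * lb)])) / peak
}
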