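#' Validate and normalise a set of RNA sequences
#'
#' A sequence set is a named character vector of upper-case RNA strings over
#' `A, C, G, U`.  DNA input (`T`) is converted to RNA (`U`), case is
#' normalised, and duplicate or empty entries are rejected.
#'
#' @param x named character vector of sequences.
#' @return named character vector with class `"sequence_set"`.
#' @export
as_sequence_set <- function(x) {
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must be named by a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- chartr("acgut", "ACGUU", x)
  seqs <- chartr("T", "U", seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("non-ACGU characters in sequence(s): ", paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  structure(seqs, class = "sequence_set")
}

#' Read RNA sequences from a FASTA file
#'
#' Sequences are normalised on read: upper-cased and `T` converted to `U`.
#' Duplicate ids, empty sequences and characters outside the RNA alphabet are
#' errors, never repaired silently.
#'
#' @param path path to a FASTA file.
#' @return a [as_sequence_set()] object in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  x <- as.character(ss)
  names(x) <- sub("\\s.*$", "", names(ss))  # id = first token of header
  as_sequence_set(x)
}

#' Write a sequence set to FASTA
#'
#' @param seqs sequence set (named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequence_set(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
  invisible(path)
}

mandatory_metadata_cols <- c("id", "organism_genus", "organism_species",
                             "strain", "contig", "start", "end", "strand")

#' Read an aptamer metadata table (TSV)
#'
#' Mandatory columns: `id`, `organism_genus`, `organism_species`, `strain`,
#' `contig`, `start`, `end`, `strand`.  Coordinates are 1-based inclusive;
#' `start <= end` and `strand` in `{+, -}` are enforced with the offending row
#' number reported.  Unknown columns are preserved untouched.
#'
#' @param path path to a tab-separated file with a header line.
#' @return data.frame of typed rows.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(mandatory_metadata_cols, names(df))
  if (length(missing))
    stop("metadata is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_coordinates(df, "metadata")
  df
}

validate_coordinates <- function(df, what) {
  bad <- which(df$start > df$end)
  if (length(bad))
    stop(what, ": start > end at row ", bad[1])
  badstrand <- which(!df$strand %in% c("+", "-"))
  if (length(badstrand))
    stop(what, ": invalid strand '", df$strand[badstrand[1]], "' at row ",
         badstrand[1], " (allowed values: +, -)")
  invisible(df)
}

#' Write a metadata table as TSV
#' @param meta data.frame as returned by [read_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from TSV or BED
#'
#' The internal coordinate convention is 1-based inclusive.  BED input
#' (0-based half-open) is converted at the boundary: a BED row with
#' `start0 = 99, end0 = 200` becomes internal `start = 100, end = 200`.
#' TSV input needs a header with columns `contig`, `start`, `end`, `strand`,
#' `product` and is taken as already 1-based inclusive.
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"tsv"` or `"bed"`.
#' @return data.frame with columns contig, start, end, strand, product.
#' @export
read_gene_annotations <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6)
      stop("BED gene annotations need 6 columns (chrom start end name score strand)")
    df <- data.frame(contig = df[[1]], start = as.integer(df[[2]]) + 1L,
                     end = as.integer(df[[3]]), strand = df[[6]],
                     product = df[[4]], stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "start", "end", "strand", "product")
    missing <- setdiff(need, names(df))
    if (length(missing))
      stop("gene annotation table is missing column(s): ",
           paste(missing, collapse = ", "))
    df <- df[need]
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
  }
  validate_coordinates(df, "gene annotations")
  df
}

#' Construct a pairwise similarity matrix object
#'
#' Carries the symmetric score matrix together with its orientation: some
#' metrics are similarity-like (higher = more similar), others distance-like.
#' All thresholding downstream respects the flag.
#'
#' @param values square numeric matrix with identical row/column names.
#' @param metric_name label for the metric that produced the scores.
#' @param higher_is_similar logical orientation flag.
#' @return object of class `"similarity_matrix"`.
#' @export
similarity_matrix <- function(values, metric_name = "external",
                              higher_is_similar = TRUE) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("values must be a square matrix")
  ids <- rownames(values)
  if (is.null(ids) || !identical(ids, colnames(values)))
    stop("values must carry identical row and column names (ids)")
  if (anyDuplicated(ids)) stop("duplicate ids in similarity matrix")
  if (max(abs(values - t(values))) > 1e-9)
    stop("similarity matrix is asymmetric beyond tolerance 1e-9")
  values <- (values + t(values)) / 2
  structure(list(ids = ids, values = values, metric_name = metric_name,
                 higher_is_similar = isTRUE(higher_is_similar)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix:", length(x$ids), "ids, metric", x$metric_name,
      if (x$higher_is_similar) "(higher = more similar)\n" else
        "(lower = more similar)\n")
  invisible(x)
}

#' Read a pairwise score matrix from TSV
#'
#' Two layouts are accepted.  Square: ids as header and first column.
#' Long: three columns `id_a`, `id_b`, `score`; every unordered pair must be
#' present, and duplicate `(a,b)` / `(b,a)` rows must agree within `1e-9`.
#'
#' @param path input path.
#' @param higher_is_similar orientation flag for the metric (see
#'   [similarity_matrix()]).
#' @param metric_name label stored with the matrix.
#' @return a [similarity_matrix()] object.
#' @export
read_score_matrix <- function(path, higher_is_similar = TRUE,
                              metric_name = "external") {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) == 3 && all(header == c("id_a", "id_b", "score"))) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    ids <- sort(unique(c(df$id_a, df$id_b)))
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    for (r in seq_len(nrow(df))) {
      a <- df$id_a[r]; b <- df$id_b[r]; s <- df$score[r]
      prev <- m[a, b]
      if (!is.na(prev) && abs(prev - s) > 1e-9)
        stop("asymmetric long-format scores for pair (", a, ", ", b, "): ",
             prev, " vs ", s)
      m[a, b] <- s; m[b, a] <- s
    }
    diag(m)[is.na(diag(m))] <- 0
    miss <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    if (nrow(miss))
      stop("missing score for pair (", ids[miss[1, 1]], ", ",
           ids[miss[1, 2]], ")")
    similarity_matrix(m, metric_name, higher_is_similar)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!identical(colnames(m), ids))
      stop("square score matrix: header ids do not match first-column ids")
    rownames(m) <- ids
    storage.mode(m) <- "double"
    similarity_matrix(m, metric_name, higher_is_similar)
  }
}

#' Write a similarity matrix as a long-format TSV
#' @param sm a [similarity_matrix()] object.
#' @param path output path.
#' @export
write_score_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "similarity_matrix"))
  idx <- which(upper.tri(sm$values), arr.ind = TRUE)
  ord <- order(sm$ids[idx[, 1]], sm$ids[idx[, 2]])
  idx <- idx[ord, , drop = FALSE]
  df <- data.frame(id_a = sm$ids[idx[, 1]], id_b = sm$ids[idx[, 2]],
                   score = signif(sm$values[idx], 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline result table as CSV
#'
#' Deterministic contract: rows are sorted (threshold, then group, then id as
#' applicable), floats are written at 6 significant digits, and writing the
#' same object twice yields byte-identical files.
#'
#' @param x result object (density curve, edge list, partition, consensus or
#'   stability report -- all are data frames underneath).
#' @param path output path.
#' @export
write_csv_output <- function(x, path) {
  df <- as.data.frame(x)
  sortcols <- intersect(c("threshold", "group", "group_a", "group_b",
                          "cluster", "algorithm", "replicate", "id", "node"),
                        names(df))
  if (length(sortcols))
    df <- df[do.call(order, df[sortcols]), , drop = FALSE]
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
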