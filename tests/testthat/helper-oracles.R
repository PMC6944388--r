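# Independent brute-force oracles used to pin the dynamic programs.
# These enumerate the full solution space recursively and never share code
# with the implementations they check.

# optimal global alignment score by exhaustive enumeration of all alignments
enum_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  rec <- function(i, j) {
    if (i > nchar(a) && j > nchar(b)) return(0)
    best <- -Inf
    if (i <= nchar(a) && j <= nchar(b)) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= nchar(a)) best <- max(best, gap + rec(i + 1, j))
    if (j <= nchar(b)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# maximum nested base-pair count by exhaustive enumeration of structures
enum_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- function(x, y) paste0(x, y) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)                     # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (ok(ch[i], ch[k]))
        best <- max(best, 1 + rec(i + 1, k - 1) +
                      if (k < j) rec(k + 1, j) else 0)
    }
    best
  }
  if (length(ch) < min_loop + 2) return(0)
  rec(1, length(ch))
}

# all valid dot-bracket structures of length n under the hairpin constraint
enum_structures <- function(n, min_loop = 3) {
  rec <- function(i, j) {
    if (j < i) return("")
    if (j - i < min_loop + 1) return(strrep(".", j - i + 1))
    out <- paste0(".", rec(i + 1, j))
    for (k in (i + min_loop + 1):j) {
      inner <- rec(i + 1, k - 1)
      rest <- if (k < j) rec(k + 1, j) else ""
      out <- c(out, as.vector(outer(paste0("(", inner, ")"), rest, paste0)))
    }
    unique(out)
  }
  rec(1, n)
}

# exact two-sided rank-sum p-value by enumeration of all rank assignments
enum_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  ws <- utils::combn(n, n1, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
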