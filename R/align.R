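#' Pairwise alignment objects
#'
#' Internal constructor for the alignment record shared by the global aligner
#' and the local hit search. Coordinates are 0-based half-open on the plus
#' strand of each genome; for minus-strand hits the aligned `a2` string is
#' the reverse complement of the plus-strand slice `g2_start:g2_end`.
#'
#' @noRd
pairwise_alignment <- function(g1_id, g2_id, g1_start, g1_end, g2_start, g2_end,
                               strand, a1, a2, score) {
  stopifnot(nchar(a1) == nchar(a2))
  cols <- .aln_columns_cpp(a1, a2)
  n_match <- sum(cols == 0L)
  n_mismatch <- sum(cols == 1L)
  n_gapcols <- sum(cols == 2L)
  len <- length(cols)
  structure(list(
    g1_id = g1_id, g2_id = g2_id,
    g1_start = as.integer(g1_start), g1_end = as.integer(g1_end),
    g2_start = as.integer(g2_start), g2_end = as.integer(g2_end),
    strand = strand, a1 = a1, a2 = a2, score = score,
    n_match = n_match, n_mismatch = n_mismatch, n_gapcols = n_gapcols,
    length = len, identity = if (len > 0) n_match / len else 0
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "alignment %s[%d,%d) x %s[%d,%d) strand %s: %d cols, %.1f%% id, score %g\n",
    x$g1_id, x$g1_start, x$g1_end, x$g2_id, x$g2_start, x$g2_end,
    x$strand, x$length, 100 * x$identity, x$score))
  invisible(x)
}

#' Global alignment of two sequences (affine gaps)
#'
#' Optimal global alignment under the Needleman-Wunsch-Gotoh recurrence with
#' blast-style affine gap costs (a gap of length L costs
#' `gap_open + L * gap_extend`). Traceback ties are broken deterministically:
#' match/mismatch over a gap in `s2` over a gap in `s1`.
#'
#' @param s1,s2 DNA strings (each non-empty, at most 10 kb; chunk longer
#'   inputs before calling).
#' @param scoring a [scoring_scheme].
#' @return A `pairwise_alignment` object.
#' @examples
#' global_align("ACGT", "ACGA", scoring_standard())
#' @export
global_align <- function(s1, s2, scoring = scoring_standard()) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  s1 <- toupper(s1); s2 <- toupper(s2)
  if (!nzchar(s1) || !nzchar(s2)) stop("sequences must be non-empty")
  if (nchar(s1) > 10000 || nchar(s2) > 10000)
    stop("sequences longer than 10 kb: chunk the input before global alignment")
  r <- .nw_align_cpp(s1, s2, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  pairwise_alignment("s1", "s2", 0L, nchar(s1), 0L, nchar(s2), "+",
                     r$a1, r$a2, r$score)
}

#' Seed-and-extend local alignment between two genomes
#'
#' Exact-match seeds of `word_size` are located on both strands of `g2`,
#' extended without gaps under an X-drop rule, merged when redundant
#' (overlap of at least 50 percent on both genomes within 30 diagonals,
#' keeping the higher-scoring hit), realigned with a banded affine local
#' aligner, and optionally trimmed at the termini to the maximal-scoring
#' block whose break-even identity is `trim_identity` (sharpens hit
#' boundaries at transitions into flanking lower-identity homology). Hits
#' shorter than `min_len` alignment columns or below `min_identity` are
#' discarded.
#'
#' @param g1,g2 [genome] objects or DNA strings.
#' @param scoring a [scoring_scheme].
#' @param min_len minimum alignment length in columns.
#' @param min_identity minimum fraction of matching columns (gap columns
#'   count as non-matches).
#' @param both_strands search the minus strand of `g2` as well.
#' @param trim_identity break-even identity for terminal trimming; `NULL`
#'   defaults to `min_identity - 0.025` (slightly below the reporting
#'   threshold, so isolated mismatch clusters at the hit termini are kept
#'   while flanking homology ten or more points below threshold is
#'   clipped); 0 disables trimming.
#' @param xdrop_mult X-drop threshold as a multiple of the match reward.
#' @param band band half-width for the gapped realignment.
#' @param diag_window diagonal distance within which overlapping hits merge.
#' @return A data.frame of hits sorted by `g1_start` with columns
#'   `g1_id`, `g2_id`, `g1_start`, `g1_end`, `g2_start`, `g2_end`, `strand`,
#'   `length`, `n_match`, `n_mismatch`, `n_gapcols`, `identity`, `score`,
#'   `a1`, `a2` (0-based half-open coordinates).
#' @export
find_local_hits <- function(g1, g2, scoring = scoring_standard(),
                            min_len = 100L, min_identity = 0.9,
                            both_strands = TRUE, trim_identity = NULL,
                            xdrop_mult = 20, band = 50L, diag_window = 30L) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  g1 <- .as_genome(g1, "g1"); g2 <- .as_genome(g2, "g2")
  if (nchar(g1$seq) < scoring$word_size || nchar(g2$seq) < scoring$word_size)
    stop("sequences must be at least word_size long")
  if (is.null(trim_identity))
    trim_identity <- if (min_identity > 0.35) min_identity - 0.025 else 0
  df <- .local_hits_cpp(g1$seq, g2$seq,
                        scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend,
                        scoring$word_size, xdrop_mult,
                        as.integer(band), as.integer(diag_window),
                        as.integer(min_len), min_identity, trim_identity,
                        both_strands)
  df <- cbind(data.frame(g1_id = rep(g1$id, nrow(df)),
                         g2_id = rep(g2$id, nrow(df)),
                         stringsAsFactors = FALSE), df)
  df
}

#' Extract one hit row as a `pairwise_alignment`
#'
#' @param hits data.frame from [find_local_hits()].
#' @param i row index.
#' @return A `pairwise_alignment` object.
#' @export
hit_alignment <- function(hits, i = 1L) {
  h <- hits[i, ]
  pairwise_alignment(h$g1_id, h$g2_id, h$g1_start, h$g1_end,
                     h$g2_start, h$g2_end, h$strand, h$a1, h$a2, h$score)
}

#' Windowed identity profile of an alignment
#'
#' Tiles the alignment columns in successive non-overlapping windows of
#' `window_len` columns (the trailing partial window is dropped) and reports
#' the identity of each window; gap columns count as non-matches.
#'
#' @param aln a `pairwise_alignment`, or any list/row with aligned strings
#'   `a1` and `a2`.
#' @param window_len window length in alignment columns.
#' @return data.frame with columns `col_start` (0-based) and `identity`,
#'   with attribute `window_len`.
#' @export
window_profile <- function(aln, window_len = 50L) {
  cols <- .aln_columns_cpp(as.character(aln$a1), as.character(aln$a2))
  window_cols_profile(cols, window_len)
}

window_cols_profile <- function(cols, window_len = 50L) {
  window_len <- as.integer(window_len)
  L <- length(cols)
  if (L < window_len)
    stop("alignment shorter than one window (", window_len, " columns)")
  n_win <- L %/% window_len
  idx <- seq_len(n_win * window_len)
  m <- matrix(cols[idx] == 0L, nrow = window_len)
  out <- data.frame(col_start = (seq_len(n_win) - 1L) * window_len,
                    identity = colMeans(m))
  attr(out, "window_len") <- window_len
  attr(out, "n_match_windows") <- sum(m)
  out
}

#' Write a hit table as blast-like TSV
#'
#' Columns mirror tabular blast output (`qid sid pident length mismatch
#' gapcols qstart qend sstart send strand score`); coordinates are written
#' 1-based inclusive.
#'
#' @param hits data.frame from [find_local_hits()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(
    qid = hits$g1_id, sid = hits$g2_id,
    pident = round(100 * hits$identity, 2),
    length = hits$length, mismatch = hits$n_mismatch, gapcols = hits$n_gapcols,
    qstart = hits$g1_start + 1L, qend = hits$g1_end,
    sstart = hits$g2_start + 1L, send = hits$g2_end,
    strand = hits$strand, score = hits$score,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
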