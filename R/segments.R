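#' Perfect-identity segment distribution of an alignment
#'
#' Decomposes an alignment into maximal runs of consecutive matching
#' columns; any mismatch or gap column breaks a run. Run lengths are in bp
#' of strict identity.
#'
#' @param aln a `pairwise_alignment`, or any list/row with aligned strings
#'   `a1`, `a2`.
#' @return An object of class `segment_distribution`: list with
#'   `segment_lengths` (integer vector in alignment order), `longest`
#'   (0 when no match column exists) and `mean_identity` (percent over all
#'   columns).
#' @export
perfect_segments <- function(aln) {
  cols <- .aln_columns_cpp(as.character(aln$a1), as.character(aln$a2))
  r <- rle(cols == 0L)
  lens <- r$lengths[r$values]
  structure(list(
    segment_lengths = as.integer(lens),
    longest = if (length(lens)) max(lens) else 0L,
    mean_identity = if (length(cols)) 100 * mean(cols == 0L) else NA_real_
  ), class = "segment_distribution")
}

#' @export
print.segment_distribution <- function(x, ...) {
  cat(sprintf(
    "%d perfect-identity segment(s), longest %d bp, mean identity %.1f%%\n",
    length(x$segment_lengths), x$longest, x$mean_identity))
  invisible(x)
}

#' Count segments at least as long as a MEPS threshold
#'
#' MEPS (minimal efficient pairing segment) is the minimal length of strict
#' identity needed to initiate recombinational pairing: about 23-27 bp for
#' the phage single-strand annealing recombinase Red-beta and 31-34 bp for
#' RecA. The count of perfect-identity segments at or above a MEPS length
#' indexes how many initiation sites a homology region offers.
#'
#' @param dist a `segment_distribution` from [perfect_segments()].
#' @param meps_len MEPS length in bp (defaults: 23 for Red-beta, 31 for
#'   RecA are the customary lower bounds).
#' @return integer count of segments with length >= `meps_len`.
#' @export
meps_count <- function(dist, meps_len) {
  stopifnot(meps_len > 0)
  sum(dist$segment_lengths >= meps_len)
}
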