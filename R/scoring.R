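#' Alignment scoring schemes
#'
#' A scoring scheme bundles the match reward, mismatch penalty, affine gap
#' costs and the exact-match seed length used by the local aligner. A gap of
#' length L costs `gap_open + L * gap_extend` (blast-style accounting).
#'
#' Two presets are provided. [scoring_standard()] is a megablast-like scheme
#' (match +1, mismatch -2, gap open 5, extend 2, word 11) used for mosaic
#' detection at the >90 percent identity threshold. [scoring_relaxed()]
#' (match +3, mismatch -4, gap open 5, extend 2, word 10) is the
#' divergence-tolerant scheme used for the ANI screen and the phage-host
#' homology search; its break-even identity of 4/7 lets fragment alignments
#' reach down to roughly 60 percent identity.
#'
#' @param match positive integer match reward.
#' @param mismatch negative integer mismatch penalty.
#' @param gap_open non-negative integer gap opening cost.
#' @param gap_extend positive integer per-base gap extension cost.
#' @param word_size integer exact-match seed length (>= 4).
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme(1, -2, 5, 2, 11)
#' scoring_relaxed()
#' @export
scoring_scheme <- function(match, mismatch, gap_open, gap_extend, word_size) {
  stopifnot(
    is.numeric(match), length(match) == 1L, match > 0,
    is.numeric(mismatch), length(mismatch) == 1L, mismatch < 0,
    is.numeric(gap_open), length(gap_open) == 1L,
    is.numeric(gap_extend), length(gap_extend) == 1L,
    gap_open >= gap_extend, gap_extend > 0,
    is.numeric(word_size), length(word_size) == 1L, word_size >= 4
  )
  if (word_size > 15) stop("word_size must be <= 15")
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         word_size = as.integer(word_size)),
    class = "scoring_scheme"
  )
}

#' @rdname scoring_scheme
#' @export
scoring_standard <- function() scoring_scheme(1L, -2L, 5L, 2L, 11L)

#' @rdname scoring_scheme
#' @export
scoring_relaxed <- function() scoring_scheme(3L, -4L, 5L, 2L, 10L)

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "scoring_scheme: match %+d, mismatch %+d, gap open %d, gap extend %d, word %d\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend, x$word_size))
  invisible(x)
}
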