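#' Extract the 2-kb flanking sequences of a mosaic
#'
#' Flanks are taken outward from the mosaic boundaries on each genome,
#' following the mosaic's strand: for a minus-strand mosaic the flank on
#' `g2` is the reverse complement of the corresponding plus-strand slice, so
#' that `left`/`right` are always relative to the `g1` orientation and the
#' two sequences of a flank pair face the same boundary. A flank shorter
#' than `flank_len` (a genome end) is flagged truncated; flanks shorter than
#' `min_flank` are untestable.
#'
#' @param mosaic one-row data.frame (or list) with `g1_start`, `g1_end`,
#'   `g2_start`, `g2_end`, `strand`.
#' @param g1,g2 [genome] objects or DNA strings.
#' @param flank_len flank length in bp.
#' @param min_flank minimum testable flank length in bp.
#' @return list with elements `left` and `right`, each a list
#'   `(s1, s2, truncated, testable)`.
#' @export
extract_flanks <- function(mosaic, g1, g2, flank_len = 2000L, min_flank = 500L) {
  g1 <- .as_genome(g1, "g1"); g2 <- .as_genome(g2, "g2")
  L1 <- nchar(g1$seq); L2 <- nchar(g2$seq)
  s1l <- substr(g1$seq, max(0L, mosaic$g1_start - flank_len) + 1L, mosaic$g1_start)
  s1r <- substr(g1$seq, mosaic$g1_end + 1L,
                min(L1, mosaic$g1_end + flank_len))
  if (identical(mosaic$strand, "-")) {
    # left of the alignment corresponds to the distal (right) side on g2 plus
    s2l <- revcomp(substr(g2$seq, mosaic$g2_end + 1L,
                          min(L2, mosaic$g2_end + flank_len)))
    s2r <- revcomp(substr(g2$seq, max(0L, mosaic$g2_start - flank_len) + 1L,
                          mosaic$g2_start))
  } else {
    s2l <- substr(g2$seq, max(0L, mosaic$g2_start - flank_len) + 1L,
                  mosaic$g2_start)
    s2r <- substr(g2$seq, mosaic$g2_end + 1L,
                  min(L2, mosaic$g2_end + flank_len))
  }
  mk <- function(s1, s2) {
    list(s1 = s1, s2 = s2,
         truncated = nchar(s1) < flank_len || nchar(s2) < flank_len,
         testable = nchar(s1) >= min_flank && nchar(s2) >= min_flank)
  }
  list(left = mk(s1l, s2l), right = mk(s1r, s2r))
}

.side_trace <- function(s1, s2, boundary, scoring, window_len, delta,
                        proximal_cols, b_method, b_fixed) {
  aln <- global_align(s1, s2, scoring)
  cols <- .aln_columns_cpp(aln$a1, aln$a2)
  # anchor the window grid at the mosaic boundary: for the left flank the
  # boundary is the alignment's right end, so reverse the columns
  if (boundary == "right") cols <- rev(cols)
  prof <- window_cols_profile(cols, window_len)
  b <- if (b_method == "fixed") b_fixed else median(prof$identity)
  guard <- (b + delta) < 1 - 1 / window_len
  qual <- prof[prof$col_start < proximal_cols &
                 prof$identity >= b + delta & guard, , drop = FALSE]
  list(b = b, profile = prof, qualifying = qual,
       trace = nrow(qual) > 0L, guard = guard,
       best_proximal = max(prof$identity[prof$col_start < proximal_cols]))
}

#' Call traces of homologous recombination in mosaic flanks
#'
#' Each flank pair is realigned globally; the identity of successive
#' `window_len`-column windows is measured with the window grid anchored at
#' the mosaic boundary. The flank's background identity `b` is the median
#' window identity (or a fixed supplied value). A side carries an HR trace
#' when at least one window within the first `proximal_cols` columns from
#' the boundary reaches `b + delta`, provided `b + delta` stays below
#' saturation (`1 - 1/window_len`). Untestable sides (flank shorter than
#' `min_flank`) are excluded from the trace count.
#'
#' @param mosaic one-row mosaic data.frame.
#' @param g1,g2 the pair's [genome] objects.
#' @param scoring [scoring_scheme] for the flank realignment (the
#'   divergence-tolerant relaxed preset by default).
#' @param flank_len,min_flank see [extract_flanks()].
#' @param window_len window length in columns.
#' @param delta required elevation above background (absolute identity
#'   fraction, i.e. 0.10 = ten identity points).
#' @param proximal_cols how far from the mosaic boundary (in alignment
#'   columns) a qualifying window may lie.
#' @param b_method `"flank_median"` (default) estimates `b` per flank;
#'   `"fixed"` uses `b_fixed` (e.g. a pair-level background).
#' @param b_fixed background identity fraction when `b_method = "fixed"`.
#' @return list of class `trace_call`: per side `b`, window profile,
#'   qualifying windows, `trace` flag and `testable`; plus `n_traces`
#'   (over testable sides) and `n_testable_sides`.
#' @export
call_traces <- function(mosaic, g1, g2, scoring = scoring_relaxed(),
                        flank_len = 2000L, min_flank = 500L,
                        window_len = 50L, delta = 0.10,
                        proximal_cols = 200L,
                        b_method = c("flank_median", "fixed"),
                        b_fixed = NULL) {
  b_method <- match.arg(b_method)
  if (b_method == "fixed" && is.null(b_fixed))
    stop("b_fixed required when b_method = 'fixed'")
  fl <- extract_flanks(mosaic, g1, g2, flank_len, min_flank)
  sides <- list()
  for (side in c("left", "right")) {
    f <- fl[[side]]
    if (!f$testable || nchar(f$s1) < window_len || nchar(f$s2) < window_len) {
      sides[[side]] <- list(b = NA_real_, profile = NULL, qualifying = NULL,
                            trace = NA, testable = FALSE)
      next
    }
    res <- .side_trace(f$s1, f$s2,
                       boundary = if (side == "left") "right" else "left",
                       scoring, window_len, delta, proximal_cols,
                       b_method, b_fixed)
    res$testable <- TRUE
    sides[[side]] <- res
  }
  testable <- vapply(sides, function(s) isTRUE(s$testable), TRUE)
  traces <- vapply(sides, function(s) isTRUE(s$trace), TRUE)
  structure(list(left = sides$left, right = sides$right,
                 n_traces = sum(traces[testable]),
                 n_testable_sides = sum(testable)),
            class = "trace_call")
}

#' @export
print.trace_call <- function(x, ...) {
  for (side in c("left", "right")) {
    s <- x[[side]]
    if (!isTRUE(s$testable)) cat(sprintf("%-5s: untestable\n", side))
    else cat(sprintf("%-5s: b = %.3f, trace = %s (%d qualifying window(s))\n",
                     side, s$b, s$trace, nrow(s$qualifying)))
  }
  cat(sprintf("n_traces = %d over %d testable side(s)\n",
              x$n_traces, x$n_testable_sides))
  invisible(x)
}

#' Trace calls for every mosaic of a pair
#'
#' @param mosaics mosaic data.frame for one genome pair.
#' @param g1,g2 the pair's [genome] objects.
#' @param ... passed to [call_traces()].
#' @return data.frame with one row per mosaic side: `mosaic` (row index),
#'   `side`, `testable`, `b`, `best_proximal`, `trace`, plus per-mosaic
#'   columns `n_traces` and `n_testable_sides` repeated on both rows.
#' @export
call_traces_pair <- function(mosaics, g1, g2, ...) {
  rows <- list()
  for (k in seq_len(nrow(mosaics))) {
    tc <- call_traces(mosaics[k, ], g1, g2, ...)
    for (side in c("left", "right")) {
      s <- tc[[side]]
      rows[[length(rows) + 1L]] <- data.frame(
        mosaic = k, side = side, testable = isTRUE(s$testable),
        b = s$b,
        best_proximal = if (isTRUE(s$testable)) s$best_proximal else NA_real_,
        trace = if (isTRUE(s$testable)) s$trace else NA,
        n_traces = tc$n_traces, n_testable_sides = tc$n_testable_sides,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mosaic = integer(0), side = character(0),
                      testable = logical(0), b = numeric(0),
                      best_proximal = numeric(0), trace = logical(0),
                      n_traces = integer(0), n_testable_sides = integer(0)))
  do.call(rbind, rows)
}

#' Probability of observing HR traces at random
#'
#' Null model for chance traces in anchor-free flanks at background identity
#' `b`. Under the analytic (binomial) method the per-window tail probability
#' is `q = P[Binomial(window_len, b) >= ceiling(window_len * (b + delta))]`
#' and the probability of at least one trace over `windows_per_side *
#' n_testable_sides` independent windows is `1 - (1 - q)^k`. The permutation
#' method estimates the per-side probability empirically by column-shuffling
#' a supplied flank alignment. When `b + delta >= 1` the threshold is
#' unreachable and the probability is exactly 0.
#'
#' @param b background identity fraction.
#' @param windows_per_side number of windows searched per side (e.g.
#'   `proximal_cols %/% window_len`).
#' @param n_testable_sides number of testable sides summed over mosaics.
#' @param window_len window length in columns.
#' @param delta required elevation (identity fraction).
#' @param method `"binomial"` or `"permutation"`.
#' @param match_cols for the permutation method: integer column codes of a
#'   representative flank alignment (0 match, 1 mismatch, 2 gap), e.g. from
#'   `.aln_columns_cpp`-derived profiles.
#' @param n_perm number of column permutations.
#' @param seed optional integer seed for the permutation method.
#' @return probability of at least one chance trace.
#' @export
random_trace_probability <- function(b, windows_per_side, n_testable_sides,
                                     window_len = 50L, delta = 0.10,
                                     method = c("binomial", "permutation"),
                                     match_cols = NULL, n_perm = 1000L,
                                     seed = NULL) {
  method <- match.arg(method)
  stopifnot(windows_per_side >= 1, n_testable_sides >= 0, window_len >= 1)
  if (b + delta >= 1) return(0)
  if (n_testable_sides == 0) return(0)
  if (method == "binomial") {
    k <- ceiling(window_len * (b + delta))
    q <- pbinom(k - 1, window_len, b, lower.tail = FALSE)
    return(1 - (1 - q)^(windows_per_side * n_testable_sides))
  }
  if (is.null(match_cols)) stop("permutation method needs match_cols")
  if (!is.null(seed)) set.seed(seed)
  n_win <- length(match_cols) %/% window_len
  use <- min(windows_per_side, n_win)
  hit <- logical(n_perm)
  for (p in seq_len(n_perm)) {
    perm <- sample(match_cols)
    prof <- window_cols_profile(perm, window_len)
    hit[p] <- any(prof$identity[seq_len(use)] >= b + delta)
  }
  p_side <- mean(hit)
  1 - (1 - p_side)^n_testable_sides
}

#' Fraction of mosaics with at least one HR trace
#'
#' @param traces data.frame from [call_traces_pair()] (possibly concatenated
#'   over pairs, with unique mosaic keys) or any data.frame with one row per
#'   mosaic side and columns `mosaic`, `n_traces`, `n_testable_sides`.
#' @return percent of testable mosaics (>= 1 testable side) with at least
#'   one trace; `NA` when no mosaic is testable.
#' @export
trace_fraction <- function(traces) {
  if (nrow(traces) == 0L) return(NA_real_)
  key <- if ("pair" %in% names(traces))
    paste(traces$pair, traces$mosaic) else as.character(traces$mosaic)
  per <- traces[!duplicated(key), , drop = FALSE]
  per <- per[per$n_testable_sides > 0L, , drop = FALSE]
  if (nrow(per) == 0L) return(NA_real_)
  100 * mean(per$n_traces >= 1L)
}
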