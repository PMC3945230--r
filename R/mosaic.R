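#' Detect mosaics between two genomes
#'
#' Mosaics are recently exchanged segments: local hits of at least `min_len`
#' alignment columns sharing strictly more than `min_identity` identity,
#' found with the standard (megablast-like) scoring scheme. Results are
#' ordered by `g1_start`.
#'
#' @param g1,g2 [genome] objects or DNA strings (distinct genomes).
#' @param scoring a [scoring_scheme].
#' @param min_len minimum mosaic length (alignment columns).
#' @param min_identity identity threshold (strict: kept hits exceed it).
#' @param ... passed to [find_local_hits()].
#' @return data.frame of mosaics (hit-table columns of [find_local_hits()]).
#' @export
detect_mosaics <- function(g1, g2, scoring = scoring_standard(),
                           min_len = 100L, min_identity = 0.90, ...) {
  g1 <- .as_genome(g1, "g1"); g2 <- .as_genome(g2, "g2")
  hits <- find_local_hits(g1, g2, scoring, min_len = min_len,
                          min_identity = min_identity, ...)
  hits <- hits[hits$identity > min_identity & hits$length >= min_len, ,
               drop = FALSE]
  hits <- hits[order(hits$g1_start, hits$g2_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.interval_overlap_frac <- function(start, end, iv) {
  if (is.null(iv) || nrow(iv) == 0L || end <= start) return(0)
  ov <- sum(pmax(0L, pmin(end, iv[, 2]) - pmax(start, iv[, 1])))
  ov / (end - start)
}

#' Map an IS catalog onto genomes as intervals
#'
#' Each catalog sequence is located in each genome by local alignment at a
#' minimum of 90 percent identity, keeping hits that cover at least 80
#' percent of the catalog sequence.
#'
#' @param catalog list of [genome] objects (or DNA strings) for the IS
#'   elements.
#' @param genomes named list of [genome] objects.
#' @param scoring a [scoring_scheme].
#' @param min_identity,min_cov mapping thresholds.
#' @return data.frame with columns `genome_id`, `start`, `end` (0-based
#'   half-open).
#' @export
map_is_catalog <- function(catalog, genomes, scoring = scoring_standard(),
                           min_identity = 0.90, min_cov = 0.80) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id, "")
  rows <- list()
  for (iselt in catalog) {
    iselt <- .as_genome(iselt, "IS")
    is_len <- nchar(iselt$seq)
    for (g in genomes) {
      hits <- find_local_hits(iselt, g, scoring,
                              min_len = max(scoring$word_size,
                                            as.integer(min_cov * is_len)),
                              min_identity = min_identity)
      if (nrow(hits) == 0L) next
      hits <- hits[(hits$g1_end - hits$g1_start) >= min_cov * is_len, ,
                   drop = FALSE]
      if (nrow(hits) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g$id, start = hits$g2_start, end = hits$g2_end,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Remove IS-derived hits from a mosaic set
#'
#' A mosaic is removed when at least half of its span on either genome
#' overlaps an annotated IS interval. The IS catalog is either a data.frame
#' of per-genome intervals (`genome_id`, `start`, `end`, 0-based half-open)
#' or a list of IS sequences that is first mapped with [map_is_catalog()].
#'
#' @param mosaics data.frame from [detect_mosaics()].
#' @param genomes named list of [genome] objects (needed only for a FASTA
#'   catalog, or when genomes carry their own `is_intervals`).
#' @param is_catalog intervals data.frame, list of IS sequences, or `NULL`
#'   to use the genomes' own `is_intervals`.
#' @param max_overlap removal threshold on the overlapping fraction.
#' @return list with `kept`, `removed` (mosaic data.frames, each with an
#'   `is_overlap` column: the larger of the two per-genome overlap
#'   fractions) and `pct_is` (percent of input mosaics removed).
#' @export
filter_is <- function(mosaics, genomes = NULL, is_catalog = NULL,
                      max_overlap = 0.5) {
  if (!is.null(genomes) && is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id, "")
  if (is.null(is_catalog)) {
    iv_tabs <- list()
    if (!is.null(genomes)) for (g in genomes) {
      if (!is.null(g$is_intervals))
        iv_tabs[[length(iv_tabs) + 1L]] <- data.frame(
          genome_id = g$id, start = g$is_intervals[, 1],
          end = g$is_intervals[, 2], stringsAsFactors = FALSE)
    }
    is_catalog <- if (length(iv_tabs)) do.call(rbind, iv_tabs)
      else data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0))
  } else if (!is.data.frame(is_catalog)) {
    if (is.null(genomes)) stop("genomes are required to map a FASTA IS catalog")
    is_catalog <- map_is_catalog(is_catalog, genomes)
  }
  n <- nrow(mosaics)
  if (n == 0L || nrow(is_catalog) == 0L) {
    mosaics$is_overlap <- rep(0, n)
    return(list(kept = mosaics, removed = mosaics[0, , drop = FALSE],
                pct_is = 0))
  }
  ivs_for <- function(id) {
    sub <- is_catalog[is_catalog$genome_id == id, , drop = FALSE]
    if (nrow(sub) == 0L) NULL else cbind(sub$start, sub$end)
  }
  ov <- numeric(n)
  for (k in seq_len(n)) {
    f1 <- .interval_overlap_frac(mosaics$g1_start[k], mosaics$g1_end[k],
                                 ivs_for(mosaics$g1_id[k]))
    f2 <- .interval_overlap_frac(mosaics$g2_start[k], mosaics$g2_end[k],
                                 ivs_for(mosaics$g2_id[k]))
    ov[k] <- max(f1, f2)
  }
  mosaics$is_overlap <- ov
  removed <- mosaics[ov >= max_overlap, , drop = FALSE]
  kept <- mosaics[ov < max_overlap, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed, pct_is = 100 * nrow(removed) / n)
}

#' Mosaic density of a genome pair
#'
#' Number of mosaics per 10 kb of phage genome; the denominator genome
#' length is the mean of the two genome lengths by default.
#'
#' @param mosaics mosaic data.frame for the pair.
#' @param g1,g2 the two [genome] objects (or DNA strings).
#' @param denominator which pair length to use: `"mean"`, `"min"` or
#'   `"max"`.
#' @return mosaics per 10 kb (numeric).
#' @export
mosaic_density <- function(mosaics, g1, g2, denominator = c("mean", "min", "max")) {
  denominator <- match.arg(denominator)
  g1 <- .as_genome(g1, "g1"); g2 <- .as_genome(g2, "g2")
  lens <- c(nchar(g1$seq), nchar(g2$seq))
  L <- switch(denominator, mean = mean(lens), min = min(lens), max = max(lens))
  nrow(mosaics) / (L / 10000)
}
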