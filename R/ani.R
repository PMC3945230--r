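#' Fragment-based average nucleotide identity of a genome pair
#'
#' The smaller genome is cut into consecutive `fragment_len` pieces; each
#' fragment is aligned to the larger genome with the relaxed local-alignment
#' scheme and contributes when its best hit covers at least 70 percent of the
#' fragment. ANI is the mean percent identity of contributing best hits;
#' coverage is the percent of fragments contributing (so it is defined on the
#' smaller genome of the pair).
#'
#' @param g1,g2 [genome] objects or DNA strings.
#' @param scoring a [scoring_scheme]; the relaxed preset reaches identities
#'   down to about 60 percent.
#' @param fragment_len fragment size in bp.
#' @param min_fragment_cov fraction of the fragment the best hit must cover.
#' @return list with `g1_id`, `g2_id`, `ani` (percent, `NA` when no fragment
#'   contributes), `coverage` (percent), `n_fragments`, `n_contributing`.
#' @export
ani_coverage <- function(g1, g2, scoring = scoring_relaxed(),
                         fragment_len = 1000L, min_fragment_cov = 0.7) {
  g1 <- .as_genome(g1, "g1"); g2 <- .as_genome(g2, "g2")
  if (nchar(g1$seq) < fragment_len || nchar(g2$seq) < fragment_len)
    stop("both genomes must be at least fragment_len long")
  if (nchar(g1$seq) <= nchar(g2$seq)) { small <- g1; large <- g2 }
  else { small <- g2; large <- g1 }
  L <- nchar(small$seq)
  n_frag <- L %/% fragment_len
  ids <- numeric(0)
  n_contrib <- 0L
  for (k in seq_len(n_frag)) {
    frag <- substr(small$seq, (k - 1L) * fragment_len + 1L, k * fragment_len)
    hits <- .local_hits_cpp(frag, large$seq,
                            scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend,
                            scoring$word_size, 20, 50L, 30L,
                            scoring$word_size, 0, 0, TRUE)
    if (nrow(hits) == 0L) next
    best <- hits[which.max(hits$score), ]
    frag_cov <- (best$g1_end - best$g1_start) / fragment_len
    if (frag_cov >= min_fragment_cov) {
      n_contrib <- n_contrib + 1L
      ids <- c(ids, best$identity)
    }
  }
  list(g1_id = g1$id, g2_id = g2$id,
       ani = if (n_contrib > 0) 100 * mean(ids) else NA_real_,
       coverage = if (n_frag > 0) 100 * n_contrib / n_frag else 0,
       n_fragments = n_frag, n_contributing = n_contrib)
}

#' ANI table for a set of genome pairs
#'
#' @param genomes named list of [genome] objects.
#' @param pairs optional two-column matrix/data.frame of genome ids; default
#'   all unordered pairs.
#' @param ... passed to [ani_coverage()].
#' @return data.frame with one row per pair.
#' @export
ani_table <- function(genomes, pairs = NULL, ...) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id, "")
  if (is.null(pairs)) {
    ids <- names(genomes)
    if (length(ids) < 2L) stop("need at least two genomes")
    pairs <- t(utils::combn(ids, 2L))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- ani_coverage(genomes[[pairs[k, 1]]], genomes[[pairs[k, 2]]], ...)
    data.frame(g1_id = a$g1_id, g2_id = a$g2_id, ani = a$ani,
               coverage = a$coverage, n_fragments = a$n_fragments,
               n_contributing = a$n_contributing, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify genome pairs for the mosaic analysis
#'
#' A pair is `redundant` when ANI > 92 percent and coverage > 80 percent (the
#' lexicographically larger genome id of the pair is flagged for removal);
#' `excluded_related` when both genomes are temperate/defective (or the pair
#' is mixed with a virulent partner) with ANI > 70 and coverage > 50, or both
#' virulent with ANI > 68 and coverage > 48; otherwise `analyzed`. Closely
#' related pairs are excluded because above-background flanking homology
#' cannot be distinguished from overall relatedness.
#'
#' @param genomes named list of [genome] objects (lifestyle labels are read
#'   from them).
#' @param ani data.frame from [ani_table()] covering every pair to classify.
#' @param thresholds named list overriding the defaults
#'   (`redundant_ani`, `redundant_cov`, `td_ani`, `td_cov`, `vv_ani`,
#'   `vv_cov`).
#' @return data.frame with columns `g1_id`, `g2_id`, `ani`, `coverage`,
#'   `status`; attribute `dropped` lists genomes removed by the redundancy
#'   rule.
#' @export
classify_pairs <- function(genomes, ani, thresholds = list()) {
  th <- utils::modifyList(list(redundant_ani = 92, redundant_cov = 80,
                               td_ani = 70, td_cov = 50,
                               vv_ani = 68, vv_cov = 48), thresholds)
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id, "")
  missing <- setdiff(c(ani$g1_id, ani$g2_id), names(genomes))
  if (length(missing)) stop("genomes absent from list: ", paste(missing, collapse = ", "))
  ls_of <- vapply(genomes, function(g) g$lifestyle, "")
  status <- character(nrow(ani))
  dropped <- character(0)
  for (k in seq_len(nrow(ani))) {
    a <- ani$ani[k]; cv <- ani$coverage[k]
    l1 <- ls_of[[ani$g1_id[k]]]; l2 <- ls_of[[ani$g2_id[k]]]
    if (!is.na(a) && a > th$redundant_ani && cv > th$redundant_cov) {
      status[k] <- "redundant"
      dropped <- c(dropped, max(ani$g1_id[k], ani$g2_id[k]))
    } else if (!is.na(a) &&
               ((l1 == "virulent" && l2 == "virulent" &&
                 a > th$vv_ani && cv > th$vv_cov) ||
                (!(l1 == "virulent" && l2 == "virulent") &&
                 a > th$td_ani && cv > th$td_cov))) {
      status[k] <- "excluded_related"
    } else {
      status[k] <- "analyzed"
    }
  }
  out <- data.frame(g1_id = ani$g1_id, g2_id = ani$g2_id,
                    ani = ani$ani, coverage = ani$coverage,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "dropped") <- unique(dropped)
  out
}

#' Homology regions between a phage and a host genome
#'
#' Relaxed-scoring local search reported at a minimum mean identity over a
#' minimum length, the screen used to locate prophage-borne homology with an
#' infecting phage.
#'
#' @param phage,host [genome] objects or DNA strings.
#' @param min_len minimum region length (bp of alignment).
#' @param min_mean_id minimum mean identity fraction.
#' @param scoring a [scoring_scheme].
#' @return hit data.frame as from [find_local_hits()].
#' @export
find_homology_regions <- function(phage, host, min_len = 100L,
                                  min_mean_id = 0.70,
                                  scoring = scoring_relaxed()) {
  find_local_hits(phage, host, scoring, min_len = min_len,
                  min_identity = min_mean_id)
}
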