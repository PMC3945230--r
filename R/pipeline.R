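category_of <- function(l1, l2) {
  s <- sort(c(l1, l2))
  if (s[1] == "temperate" && s[2] == "temperate") return("T-T")
  if (s[1] == "defective" && s[2] == "temperate") return("T-D")
  if (s[1] == "defective" && s[2] == "defective") return("D-D")
  if (s[1] == "virulent" && s[2] == "virulent") return("V-V")
  if (any(s == "virulent")) return("V-other")
  NA_character_
}

CATEGORIES <- c("T-T", "T-D", "D-D", "V-V", "V-other")

#' Run the full mosaic scan on a genome set
#'
#' Orchestrates the pipeline: fragment-based ANI screen and pair
#' classification (relatedness exclusion), mosaic detection on analyzed
#' pairs, IS filtering, HR-trace calling on mosaic flanks, and category
#' summaries. Returns a classed object with `print`, `summary` and `plot`
#' methods.
#'
#' @param genomes named list of [genome] objects (e.g. from
#'   [read_genome_fasta()] or [simulate_cohort()]).
#' @param metadata optional data.frame (`id`, `lifestyle`) overriding the
#'   genomes' lifestyle labels; genomes absent from it are labeled unknown.
#' @param pairs optional two-column matrix/data.frame of genome ids to
#'   restrict the comparison; default all unordered pairs.
#' @param is_catalog IS intervals data.frame (`genome_id`, `start`, `end`),
#'   list of IS sequences, or `NULL` to use the genomes' own intervals.
#' @param scoring [scoring_scheme] for mosaic detection.
#' @param relaxed [scoring_scheme] for ANI and flank realignment.
#' @param min_len,min_identity mosaic thresholds.
#' @param flank_len,min_flank,window_len,delta,proximal_cols trace-calling
#'   parameters, see [call_traces()].
#' @param fragment_len ANI fragment size.
#' @param run_ani set `FALSE` to skip the ANI screen and analyze all pairs
#'   (useful when pairs are pre-screened).
#' @param verbose log excluded pairs and removed IS hits.
#' @return object of class `mosaic_scan` with elements `pairs` (pair-level
#'   table), `ani`, `mosaics`, `traces`, `categories`, `matrix`, `params`.
#' @export
mosaic_scan <- function(genomes, metadata = NULL, pairs = NULL,
                        is_catalog = NULL,
                        scoring = scoring_standard(),
                        relaxed = scoring_relaxed(),
                        min_len = 100L, min_identity = 0.90,
                        flank_len = 2000L, min_flank = 500L,
                        window_len = 50L, delta = 0.10,
                        proximal_cols = 200L, fragment_len = 1000L,
                        run_ani = TRUE, verbose = FALSE) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id, "")
  if (!is.null(metadata)) {
    for (k in seq_along(genomes)) {
      hit <- match(genomes[[k]]$id, metadata$id)
      genomes[[k]]$lifestyle <- if (is.na(hit)) "unknown"
        else match.arg(metadata$lifestyle[hit], LIFESTYLES)
    }
  }
  ids <- names(genomes)
  if (is.null(pairs)) {
    if (length(ids) < 2L) stop("need at least two genomes")
    pairs <- t(utils::combn(ids, 2L))
  }
  pairs <- as.matrix(pairs)

  if (run_ani) {
    ani <- ani_table(genomes, pairs, scoring = relaxed,
                     fragment_len = fragment_len)
    cls <- classify_pairs(genomes, ani)
    dropped <- attr(cls, "dropped")
  } else {
    ani <- data.frame(g1_id = pairs[, 1], g2_id = pairs[, 2],
                      ani = NA_real_, coverage = NA_real_,
                      n_fragments = NA_integer_, n_contributing = NA_integer_,
                      stringsAsFactors = FALSE)
    cls <- cbind(ani[, c("g1_id", "g2_id", "ani", "coverage")],
                 data.frame(status = "analyzed", stringsAsFactors = FALSE))
    dropped <- character(0)
  }

  pair_rows <- list(); mosaic_tabs <- list(); trace_tabs <- list()
  for (k in seq_len(nrow(cls))) {
    id1 <- cls$g1_id[k]; id2 <- cls$g2_id[k]
    g1 <- genomes[[id1]]; g2 <- genomes[[id2]]
    status <- cls$status[k]
    if (status == "analyzed" && (id1 %in% dropped || id2 %in% dropped))
      status <- "excluded_related"
    base <- data.frame(
      pair = k, g1_id = id1, g2_id = id2,
      lifestyle1 = g1$lifestyle, lifestyle2 = g2$lifestyle,
      category = category_of(g1$lifestyle, g2$lifestyle),
      ani = cls$ani[k], coverage = cls$coverage[k], status = status,
      n_blast_matches = 0L, n_is_removed = 0L, n_mosaics = 0L,
      density = NA_real_, mean_traces = NA_real_,
      stringsAsFactors = FALSE)
    if (status != "analyzed") {
      if (verbose)
        message(sprintf("pair %s x %s excluded (%s: ANI %.1f, coverage %.1f)",
                        id1, id2, status, cls$ani[k], cls$coverage[k]))
      pair_rows[[k]] <- base
      next
    }
    det <- detect_mosaics(g1, g2, scoring, min_len, min_identity)
    fi <- filter_is(det, genomes[c(id1, id2)], is_catalog)
    if (verbose && nrow(fi$removed))
      message(sprintf("pair %s x %s: %d IS-derived hit(s) removed (>=50%% IS overlap)",
                      id1, id2, nrow(fi$removed)))
    kept <- fi$kept
    tr <- call_traces_pair(kept, g1, g2, scoring = relaxed,
                           flank_len = flank_len, min_flank = min_flank,
                           window_len = window_len, delta = delta,
                           proximal_cols = proximal_cols)
    if (nrow(tr)) tr <- cbind(data.frame(pair = k), tr)
    if (nrow(kept)) {
      per_mosaic <- tr[!duplicated(tr$mosaic), c("mosaic", "n_traces",
                                                 "n_testable_sides")]
      kept$n_traces <- per_mosaic$n_traces[match(seq_len(nrow(kept)),
                                                 per_mosaic$mosaic)]
      kept$n_testable_sides <- per_mosaic$n_testable_sides[
        match(seq_len(nrow(kept)), per_mosaic$mosaic)]
      kept <- cbind(data.frame(pair = k), kept)
    }
    base$n_blast_matches <- nrow(det)
    base$n_is_removed <- nrow(fi$removed)
    base$n_mosaics <- nrow(kept)
    base$density <- mosaic_density(kept, g1, g2)
    testable <- if (nrow(kept)) kept[kept$n_testable_sides > 0L, ] else kept
    base$mean_traces <- if (NROW(testable)) mean(testable$n_traces) else NA_real_
    pair_rows[[k]] <- base
    mosaic_tabs[[k]] <- kept
    trace_tabs[[k]] <- tr
  }

  pair_tab <- do.call(rbind, pair_rows)
  mosaics <- if (length(mosaic_tabs)) do.call(rbind,
    Filter(function(x) NROW(x) > 0, mosaic_tabs)) else NULL
  traces <- if (length(trace_tabs)) do.call(rbind,
    Filter(function(x) NROW(x) > 0, trace_tabs)) else NULL
  if (is.null(mosaics)) mosaics <- data.frame()
  if (is.null(traces)) traces <- data.frame()

  categories <- summarize_categories(pair_tab, mosaics, traces,
                                     window_len = window_len, delta = delta,
                                     proximal_cols = proximal_cols)
  mat <- build_pair_matrix(ids, pair_tab)
  structure(list(genomes = ids,
                 lifestyles = vapply(genomes, function(g) g$lifestyle, ""),
                 pairs = pair_tab, ani = ani, mosaics = mosaics,
                 traces = traces, categories = categories, matrix = mat,
                 params = list(min_len = min_len, min_identity = min_identity,
                               flank_len = flank_len, min_flank = min_flank,
                               window_len = window_len, delta = delta,
                               proximal_cols = proximal_cols,
                               fragment_len = fragment_len,
                               scoring = scoring, relaxed = relaxed)),
            class = "mosaic_scan")
}

#' Summarize mosaics and traces by lifestyle category
#'
#' One row per category of genome pairs (T-T, T-D, D-D, V-V, V-other):
#' number of analyzed pairs, raw local hits, percent IS-derived hits,
#' mosaics analyzed for traces (m), mosaics per pair, median mosaic length
#' and identity, trace-count breakdown (0/1/2), and the binomial null
#' probability of observing at least one trace at random across the
#' category's searched windows.
#'
#' @param pair_tab pair-level table (as in a `mosaic_scan` object).
#' @param mosaics mosaic table with `pair`, `length`, `identity`,
#'   `n_traces`, `n_testable_sides`.
#' @param traces side-level trace table with `b` estimates.
#' @param window_len,delta,proximal_cols trace parameters used, for the
#'   null model.
#' @return data.frame with one row per category.
#' @export
summarize_categories <- function(pair_tab, mosaics, traces,
                                 window_len = 50L, delta = 0.10,
                                 proximal_cols = 200L) {
  rows <- lapply(CATEGORIES, function(cat) {
    pk <- pair_tab$pair[pair_tab$status == "analyzed" &
                          !is.na(pair_tab$category) &
                          pair_tab$category == cat]
    p <- length(pk)
    sub <- if (NROW(mosaics) && p) mosaics[mosaics$pair %in% pk, , drop = FALSE]
      else data.frame()
    tsub <- if (NROW(traces) && p) traces[traces$pair %in% pk, , drop = FALSE]
      else data.frame()
    n_blast <- sum(pair_tab$n_blast_matches[pair_tab$pair %in% pk])
    n_is <- sum(pair_tab$n_is_removed[pair_tab$pair %in% pk])
    testable <- if (NROW(sub)) sub[sub$n_testable_sides > 0L, , drop = FALSE]
      else data.frame()
    m <- NROW(testable)
    n_sides <- if (m) sum(testable$n_testable_sides) else 0L
    b_med <- if (NROW(tsub)) median(tsub$b, na.rm = TRUE) else NA_real_
    p_rand <- if (m && !is.na(b_med))
      random_trace_probability(b_med, max(1L, proximal_cols %/% window_len),
                               n_sides, window_len, delta) else NA_real_
    data.frame(
      category = cat, n_pairs = p, n_blast_matches = n_blast,
      pct_is = if (n_blast > 0) 100 * n_is / n_blast else 0,
      n_mosaics = m,
      mosaics_per_pair = if (p > 0) m / p else NA_real_,
      median_len = if (m) median(testable$length) else NA_real_,
      median_id = if (m) median(100 * testable$identity) else NA_real_,
      n_zero_trace = if (m) sum(testable$n_traces == 0L) else 0L,
      n_one_trace = if (m) sum(testable$n_traces == 1L) else 0L,
      n_two_trace = if (m) sum(testable$n_traces >= 2L) else 0L,
      pct_traced = if (m) 100 * mean(testable$n_traces >= 1L) else NA_real_,
      p_random_traces = p_rand, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

build_pair_matrix <- function(ids, pair_tab) {
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  status <- matrix("", n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(pair_tab))) {
    i <- match(pair_tab$g1_id[k], ids); j <- match(pair_tab$g2_id[k], ids)
    lo <- max(i, j); hi <- min(i, j)
    if (pair_tab$status[k] == "analyzed") {
      m[lo, hi] <- pair_tab$density[k]      # lower triangle: density
      m[hi, lo] <- pair_tab$mean_traces[k]  # upper triangle: mean traces
    }
    status[lo, hi] <- status[hi, lo] <- pair_tab$status[k]
  }
  list(values = m, status = status)
}

#' @export
print.mosaic_scan <- function(x, ...) {
  n_an <- sum(x$pairs$status == "analyzed")
  cat(sprintf("mosaic_scan: %d genomes, %d pairs (%d analyzed, %d excluded)\n",
              length(x$genomes), nrow(x$pairs), n_an, nrow(x$pairs) - n_an))
  cat(sprintf("%d mosaics kept (>%.0f%% identity, >=%d bp)",
              NROW(x$mosaics), 100 * x$params$min_identity, x$params$min_len))
  if (NROW(x$mosaics))
    cat(sprintf("; median length %.0f bp, median identity %.1f%%",
                median(x$mosaics$length), 100 * median(x$mosaics$identity)))
  cat("\n")
  tf <- trace_fraction(x$traces)
  if (!is.na(tf))
    cat(sprintf("%.0f%% of testable mosaics carry >=1 HR trace\n", tf))
  invisible(x)
}

#' @export
summary.mosaic_scan <- function(object, ...) {
  out <- object$categories
  class(out) <- c("summary.mosaic_scan", "data.frame")
  out
}

#' @export
print.summary.mosaic_scan <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Render the mosaic density / trace count pair matrix
#'
#' Lower triangle: mosaics per 10 kb; upper triangle: mean HR-trace count
#' per mosaic; excluded pairs drawn black; diagonal grey. A pure view of
#' the matrix twin: every rendered number is recomputable from the written
#' TSV.
#'
#' @param x a `mosaic_scan` object or the path to a `pair_matrix.tsv`
#'   written by [write_scan_results()].
#' @param file optional PNG path; when `NULL` draws on the active device.
#' @param main plot title.
#' @return the plotted value matrix, invisibly.
#' @export
render_matrix <- function(x, file = NULL, main = "mosaic density (lower) / mean traces (upper)") {
  if (inherits(x, "mosaic_scan")) {
    vals <- x$matrix$values; status <- x$matrix$status
  } else {
    tab <- utils::read.delim(x, check.names = FALSE)
    rn <- tab[[1]]; tab <- as.matrix(tab[, -1, drop = FALSE])
    if (nrow(tab) != ncol(tab)) stop("pair matrix must be square")
    status <- matrix("", nrow(tab), ncol(tab))
    status[tab == "excluded_related" | tab == "redundant"] <- "excluded_related"
    vals <- suppressWarnings(matrix(as.numeric(tab), nrow(tab),
                                    dimnames = list(rn, colnames(tab))))
  }
  n <- nrow(vals)
  if (!is.null(file)) {
    grDevices::png(file, width = 200 + 40 * n, height = 200 + 40 * n)
    on.exit(grDevices::dev.off())
  }
  graphics::par(mar = c(6, 6, 3, 1))
  img <- t(vals[n:1, , drop = FALSE])
  rng <- range(vals, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  graphics::image(seq_len(n), seq_len(n), img, zlim = rng,
                  col = grDevices::hcl.colors(40, "viridis"),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  excl <- which(status != "" & status != "analyzed", arr.ind = TRUE)
  if (nrow(excl))
    graphics::rect(excl[, 2] - 0.5, n - excl[, 1] + 0.5,
                   excl[, 2] + 0.5, n - excl[, 1] + 1.5, col = "black")
  graphics::rect(seq_len(n) - 0.5, n - seq_len(n) + 0.5,
                 seq_len(n) + 0.5, n - seq_len(n) + 1.5, col = "grey70")
  graphics::axis(1, seq_len(n), colnames(vals), las = 2, cex.axis = 0.7)
  graphics::axis(2, n:1, rownames(vals), las = 2, cex.axis = 0.7)
  invisible(vals)
}

#' @export
plot.mosaic_scan <- function(x, file = NULL, ...) {
  render_matrix(x, file = file)
}

#' Write all scan result tables
#'
#' Writes `pairs.tsv` (pair-level ANI/status/counts), `mosaics.tsv`,
#' `mosaics.bed` (one BED line per mosaic per genome, 0-based half-open),
#' `traces.tsv`, `categories.tsv`, `categories.json` and `pair_matrix.tsv`
#' (square; lower triangle density, upper triangle mean traces, excluded
#' pairs labeled).
#'
#' @param x a `mosaic_scan` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(x$pairs, "pairs.tsv")
  mos <- x$mosaics
  if (NROW(mos)) {
    wt(mos[, setdiff(names(mos), c("a1", "a2"))], "mosaics.tsv")
    bed <- rbind(
      data.frame(chrom = mos$g1_id, start = mos$g1_start, end = mos$g1_end,
                 name = sprintf("mosaic_p%d_%d", mos$pair, seq_len(nrow(mos))),
                 score = round(1000 * mos$identity), strand = "+"),
      data.frame(chrom = mos$g2_id, start = mos$g2_start, end = mos$g2_end,
                 name = sprintf("mosaic_p%d_%d", mos$pair, seq_len(nrow(mos))),
                 score = round(1000 * mos$identity), strand = mos$strand))
    write.table(bed, file.path(dir, "mosaics.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    wt(data.frame(), "mosaics.tsv")
  }
  wt(x$traces, "traces.tsv")
  wt(x$categories, "categories.tsv")
  jsonlite::write_json(x$categories, file.path(dir, "categories.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  vals <- x$matrix$values
  out <- matrix(as.character(vals), nrow(vals), dimnames = dimnames(vals))
  excl <- x$matrix$status != "" & x$matrix$status != "analyzed"
  out[excl] <- x$matrix$status[excl]
  out[is.na(vals) & !excl] <- "NA"
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file.path(dir, "pair_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
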