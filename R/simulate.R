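BASES <- c("A", "C", "G", "T")

codes_to_seq <- function(v) paste(BASES[v + 1L], collapse = "")

# per-site substitution probability applied independently to both genomes so
# that the expected pairwise identity equals b: (1-p)^2 + p^2/3 = b
divergence_for_background <- function(b) {
  stopifnot(b > 0.25, b <= 1)
  (2 - sqrt(4 - (16 / 3) * (1 - b))) / (8 / 3)
}

mutate_codes <- function(v, p) {
  if (p <= 0) return(v)
  hit <- runif(length(v)) < p
  n <- sum(hit)
  if (n) v[hit] <- (v[hit] + sample.int(3L, n, replace = TRUE)) %% 4L
  v
}

#' Configuration for the synthetic phage cohort generator
#'
#' Defaults describe the study conditions the rest of the package is
#' validated against: 45-kb genome pairs at 60 percent background identity
#' carrying three planted mosaics each (lognormal lengths, median 450 bp,
#' truncated to 150-800 bp, identities 95-99 percent), 200-bp recombination
#' anchors at background + 20 identity points flanking a mosaic with
#' probability 0.5 per side, optional anchor masking by a later exchange
#' with a third genome, optional shared IS-like repeats, indels off.
#'
#' @param seed integer RNG seed.
#' @param n_pairs number of genome pairs.
#' @param genome_len genome length in bp.
#' @param background_identity expected pairwise background identity `b`.
#' @param n_mosaics planted mosaics per pair.
#' @param mosaic_len_median,mosaic_len_sdlog lognormal length distribution.
#' @param mosaic_len_range truncation bounds for mosaic lengths (bp).
#' @param mosaic_identity_range uniform range of planted mosaic identities.
#' @param anchor_len anchor length in bp.
#' @param anchor_identity anchor identity; default `b + 0.20`.
#' @param p_anchor_left,p_anchor_right probability of planting an anchor on
#'   each side of a mosaic.
#' @param p_mask probability that one planted anchor of a mosaic is
#'   overwritten by unrelated sequence (a later exchange masking the trace).
#' @param n_is shared IS-like repeats planted per pair.
#' @param is_len IS repeat length in bp.
#' @param indel_rate per-bp background indel event rate on the second
#'   genome (0 keeps the two genomes colinear and analytic checks exact).
#' @param pair_lifestyles list of length-2 character vectors recycled over
#'   pairs; default cycles temperate-temperate, temperate-defective,
#'   defective-defective.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pairs = 10L, genome_len = 45000L,
                       background_identity = 0.60, n_mosaics = 3L,
                       mosaic_len_median = 450, mosaic_len_sdlog = 0.6,
                       mosaic_len_range = c(150L, 800L),
                       mosaic_identity_range = c(0.95, 0.99),
                       anchor_len = 200L, anchor_identity = NULL,
                       p_anchor_left = 0.5, p_anchor_right = 0.5,
                       p_mask = 0, n_is = 0L, is_len = 1200L,
                       indel_rate = 0,
                       pair_lifestyles = NULL) {
  if (is.null(anchor_identity)) anchor_identity <- background_identity + 0.20
  if (is.null(pair_lifestyles))
    pair_lifestyles <- list(c("temperate", "temperate"),
                            c("temperate", "defective"),
                            c("defective", "defective"))
  cfg <- list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
              genome_len = as.integer(genome_len),
              background_identity = background_identity,
              n_mosaics = as.integer(n_mosaics),
              mosaic_len_median = mosaic_len_median,
              mosaic_len_sdlog = mosaic_len_sdlog,
              mosaic_len_range = as.integer(mosaic_len_range),
              mosaic_identity_range = mosaic_identity_range,
              anchor_len = as.integer(anchor_len),
              anchor_identity = anchor_identity,
              p_anchor_left = p_anchor_left, p_anchor_right = p_anchor_right,
              p_mask = p_mask, n_is = as.integer(n_is),
              is_len = as.integer(is_len), indel_rate = indel_rate,
              pair_lifestyles = pair_lifestyles)
  with(cfg, {
    stopifnot(n_pairs >= 1, genome_len >= 1000,
              background_identity > 0.25, background_identity <= 1,
              n_mosaics >= 0, anchor_identity > 0.25, anchor_identity <= 1,
              p_anchor_left >= 0, p_anchor_left <= 1,
              p_anchor_right >= 0, p_anchor_right <= 1,
              p_mask >= 0, p_mask <= 1, n_is >= 0, is_len > 0,
              indel_rate >= 0, all(mosaic_len_range > 0),
              all(mosaic_identity_range > 0.25),
              all(mosaic_identity_range <= 1))
  })
  # feasibility: each mosaic block must hold flanks + anchors + mosaic
  margin <- 2000L + cfg$anchor_len + 200L
  if (cfg$n_mosaics > 0) {
    block <- cfg$genome_len %/% cfg$n_mosaics
    if (block < 2L * margin + max(cfg$mosaic_len_range))
      stop("infeasible config: mosaics plus flanks exceed the genome")
  }
  structure(cfg, class = "sim_config")
}

rtrunc_lnorm <- function(n, median, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, meanlog = log(median), sdlog = sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Simulate a cohort of phage genome pairs with planted ground truth
#'
#' For each pair a random ancestor is drawn and two genomes are derived by
#' independent per-site substitution calibrated so the expected pairwise
#' identity equals the configured background. Mosaics are planted by copying
#' a segment of the first genome into the second at the target identity;
#' anchors (pre-existing partial homology across which the exchange is
#' imagined to have occurred) are written flanking the mosaic; with
#' probability `p_mask` one planted anchor is overwritten by unrelated
#' sequence, emulating a later exchange with a third genome that erases the
#' trace on that side. Shared IS-like repeats are copied into both genomes
#' at unrelated positions. Fully seeded: the same config yields
#' byte-identical output.
#'
#' @param config a [sim_config].
#' @return list of class `sim_cohort` with `genomes` (named list of
#'   [genome]), `truth` (lists `pairs`, `mosaics`, `anchors`, `is`),
#'   `is_catalog` (list of IS [genome]s, possibly empty) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p_bg <- divergence_for_background(config$background_identity)
  L <- config$genome_len
  genomes <- list()
  pair_rows <- list(); mosaic_rows <- list(); anchor_rows <- list()
  is_rows <- list()
  is_catalog <- list()
  if (config$n_is > 0) {
    is_catalog[[1]] <- genome("IS_syn1",
                              codes_to_seq(sample.int(4L, config$is_len,
                                                      replace = TRUE) - 1L))
  }
  margin <- 2000L + config$anchor_len + 200L

  for (pk in seq_len(config$n_pairs)) {
    id1 <- sprintf("pair%02d_A", pk); id2 <- sprintf("pair%02d_B", pk)
    ls <- config$pair_lifestyles[[(pk - 1L) %% length(config$pair_lifestyles) + 1L]]
    anc <- sample.int(4L, L, replace = TRUE) - 1L
    gA <- mutate_codes(anc, p_bg)
    gB <- mutate_codes(anc, p_bg)
    planted <- matrix(integer(0), ncol = 2)  # zones to protect (0-based)

    n_m <- config$n_mosaics
    lens <- if (n_m > 0) rtrunc_lnorm(n_m, config$mosaic_len_median,
                                      config$mosaic_len_sdlog,
                                      config$mosaic_len_range) else integer(0)
    block <- if (n_m > 0) L %/% n_m else L
    for (mk in seq_len(n_m)) {
      lo <- (mk - 1L) * block + margin
      hi <- mk * block - margin - lens[mk]
      start <- lo + sample.int(hi - lo + 1L, 1L) - 1L   # 0-based
      end <- start + lens[mk]
      idn <- runif(1, config$mosaic_identity_range[1],
                   config$mosaic_identity_range[2])
      seg <- gA[(start + 1L):end]
      gB[(start + 1L):end] <- mutate_codes(seg, 1 - idn)
      realized <- mean(gA[(start + 1L):end] == gB[(start + 1L):end])
      has_left <- runif(1) < config$p_anchor_left
      has_right <- runif(1) < config$p_anchor_right
      for (side in c("left", "right")) {
        has <- if (side == "left") has_left else has_right
        if (!has) next
        a0 <- if (side == "left") start - config$anchor_len else end
        a1 <- a0 + config$anchor_len
        aseg <- gA[(a0 + 1L):a1]
        gB[(a0 + 1L):a1] <- mutate_codes(aseg, 1 - config$anchor_identity)
        anchor_rows[[length(anchor_rows) + 1L]] <- data.frame(
          pair = pk, mosaic = mk, side = side,
          g1_start = a0, g1_end = a1, g2_start = a0, g2_end = a1,
          identity = mean(gA[(a0 + 1L):a1] == gB[(a0 + 1L):a1]),
          masked = FALSE, stringsAsFactors = FALSE)
      }
      masked_side <- NA_character_
      if ((has_left || has_right) && runif(1) < config$p_mask) {
        cand <- c("left", "right")[c(has_left, has_right)]
        masked_side <- if (length(cand) == 1L) cand else sample(cand, 1L)
        a0 <- if (masked_side == "left") start - config$anchor_len else end
        a1 <- a0 + config$anchor_len
        gB[(a0 + 1L):a1] <- sample.int(4L, config$anchor_len, replace = TRUE) - 1L
        last <- length(anchor_rows)
        for (q in seq_len(last)) {
          r <- anchor_rows[[q]]
          if (r$pair == pk && r$mosaic == mk && r$side == masked_side)
            anchor_rows[[q]]$masked <- TRUE
        }
      }
      mosaic_rows[[length(mosaic_rows) + 1L]] <- data.frame(
        pair = pk, g1_id = id1, g2_id = id2, mosaic = mk,
        g1_start = start, g1_end = end, g2_start = start, g2_end = end,
        length = lens[mk], identity = realized,
        anchor_left = has_left, anchor_right = has_right,
        masked_side = masked_side, stringsAsFactors = FALSE)
      planted <- rbind(planted,
                       c(start - margin, end + margin))
    }

    # shared IS-like repeats at unrelated positions in both genomes
    if (config$n_is > 0) {
      is_codes <- match(strsplit(is_catalog[[1]]$seq, "")[[1]], BASES) - 1L
      free_pos <- function() {
        for (try in 1:1000) {
          s <- sample.int(L - config$is_len - 1L, 1L)
          ok <- TRUE
          if (nrow(planted)) {
            ov <- pmin(s + config$is_len, planted[, 2]) > pmax(s, planted[, 1])
            ok <- !any(ov)
          }
          if (ok) return(s)
        }
        stop("infeasible config: no room for IS copies")
      }
      for (ik in seq_len(config$n_is)) {
        sA <- free_pos(); sB <- free_pos()
        gA[(sA + 1L):(sA + config$is_len)] <- is_codes
        gB[(sB + 1L):(sB + config$is_len)] <- is_codes
        is_rows[[length(is_rows) + 1L]] <- data.frame(
          genome_id = id1, start = sA, end = sA + config$is_len,
          stringsAsFactors = FALSE)
        is_rows[[length(is_rows) + 1L]] <- data.frame(
          genome_id = id2, start = sB, end = sB + config$is_len,
          stringsAsFactors = FALSE)
        planted <- rbind(planted, c(sA - 100L, sA + config$is_len + 100L),
                         c(sB - 100L, sB + config$is_len + 100L))
      }
    }

    # background realized identity over non-planted sites
    bg_mask <- rep(TRUE, L)
    if (nrow(planted)) for (q in seq_len(nrow(planted))) {
      from <- max(1L, planted[q, 1] + 1L); to <- min(L, planted[q, 2])
      if (from <= to) bg_mask[from:to] <- FALSE
    }
    bg_real <- mean(gA[bg_mask] == gB[bg_mask])

    # optional background indels on the second genome
    if (config$indel_rate > 0) {
      allowed <- which(bg_mask)
      n_ev <- stats::rpois(1, config$indel_rate * L)
      if (n_ev > 0) {
        pos <- sort(sample(allowed, min(n_ev, length(allowed))),
                    decreasing = TRUE)
        shifts <- data.frame(pos = integer(0), shift = integer(0))
        for (pz in pos) {
          len <- stats::rgeom(1, 1 / 3) + 1L
          if (runif(1) < 0.5) {  # deletion
            len <- min(len, length(gB) - pz)
            if (len < 1L) next
            gB <- gB[-((pz + 1L):(pz + len))]
            shifts <- rbind(shifts, data.frame(pos = pz, shift = -len))
          } else {               # insertion
            ins <- sample.int(4L, len, replace = TRUE) - 1L
            gB <- append(gB, ins, after = pz)
            shifts <- rbind(shifts, data.frame(pos = pz, shift = len))
          }
        }
        remap <- function(x) {
          vapply(x, function(xx)
            xx + sum(shifts$shift[shifts$pos < xx]), numeric(1))
        }
        for (q in seq_along(mosaic_rows)) if (mosaic_rows[[q]]$pair == pk) {
          mosaic_rows[[q]]$g2_start <- remap(mosaic_rows[[q]]$g2_start)
          mosaic_rows[[q]]$g2_end <- remap(mosaic_rows[[q]]$g2_end)
        }
        for (q in seq_along(anchor_rows)) if (anchor_rows[[q]]$pair == pk) {
          anchor_rows[[q]]$g2_start <- remap(anchor_rows[[q]]$g2_start)
          anchor_rows[[q]]$g2_end <- remap(anchor_rows[[q]]$g2_end)
        }
        for (q in seq_along(is_rows)) if (is_rows[[q]]$genome_id == id2) {
          is_rows[[q]]$start <- remap(is_rows[[q]]$start)
          is_rows[[q]]$end <- remap(is_rows[[q]]$end)
        }
      }
    }

    iv1 <- do.call(rbind, lapply(is_rows, function(r)
      if (r$genome_id == id1) c(r$start, r$end) else NULL))
    iv2 <- do.call(rbind, lapply(is_rows, function(r)
      if (r$genome_id == id2) c(r$start, r$end) else NULL))
    genomes[[id1]] <- genome(id1, codes_to_seq(gA), ls[1], iv1)
    genomes[[id2]] <- genome(id2, codes_to_seq(gB), ls[2], iv2)
    pair_rows[[pk]] <- data.frame(
      pair = pk, g1_id = id1, g2_id = id2,
      lifestyle1 = ls[1], lifestyle2 = ls[2],
      background = bg_real, stringsAsFactors = FALSE)
  }

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  truth <- list(
    pairs = do.call(rbind, pair_rows),
    mosaics = bind(mosaic_rows, data.frame(
      pair = integer(0), g1_id = character(0), g2_id = character(0),
      mosaic = integer(0), g1_start = integer(0), g1_end = integer(0),
      g2_start = integer(0), g2_end = integer(0), length = integer(0),
      identity = numeric(0), anchor_left = logical(0),
      anchor_right = logical(0), masked_side = character(0))),
    anchors = bind(anchor_rows, data.frame(
      pair = integer(0), mosaic = integer(0), side = character(0),
      g1_start = integer(0), g1_end = integer(0), g2_start = integer(0),
      g2_end = integer(0), identity = numeric(0), masked = logical(0))),
    is = bind(is_rows, data.frame(genome_id = character(0),
                                  start = integer(0), end = integer(0))))
  structure(list(genomes = genomes, truth = truth,
                 is_catalog = is_catalog, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d pairs (%d genomes of %d bp), b = %.2f, %d planted mosaics, %d anchors, %d IS copies\n",
    x$config$n_pairs, length(x$genomes), x$config$genome_len,
    x$config$background_identity, nrow(x$truth$mosaics),
    nrow(x$truth$anchors), nrow(x$truth$is)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `genomes.fasta`, `metadata.tsv`, the truth tables
#' (`truth_mosaics.tsv`, `truth_anchors.tsv`, `truth_is.tsv`, `truth.json`)
#' and, when IS repeats were planted, `is_catalog.fasta`.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genomes_fasta(cohort$genomes, file.path(dir, "genomes.fasta"))
  md <- data.frame(id = names(cohort$genomes),
                   lifestyle = vapply(cohort$genomes, function(g) g$lifestyle, ""),
                   stringsAsFactors = FALSE)
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$truth$mosaics, file.path(dir, "truth_mosaics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth$anchors, file.path(dir, "truth_anchors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth$is, file.path(dir, "truth_is.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (length(cohort$is_catalog))
    write_genomes_fasta(cohort$is_catalog, file.path(dir, "is_catalog.fasta"))
  invisible(dir)
}

.recip_overlap_match <- function(ds, de, ts, te, slack) {
  ov <- min(de, te) - max(ds, ts)
  if (ov <= 0) return(FALSE)
  (ov / (de - ds) >= 0.8 && ov / (te - ts) >= 0.8) ||
    (abs(ds - ts) <= slack && abs(de - te) <= slack)
}

#' Score detections against planted truth
#'
#' A detected mosaic matches a truth mosaic of the same pair when the two
#' intervals overlap reciprocally by at least 80 percent on both genomes (or
#' both boundaries agree within `slack` bp). Matching is greedy, one-to-one.
#' When side-level trace calls are supplied, trace recall is measured over
#' testable sides of matched mosaics carrying an unmasked planted anchor,
#' and trace precision over all called traces on matched testable sides.
#'
#' @param mosaics detected mosaic data.frame carrying `g1_id`/`g2_id`
#'   matching the truth pair ids (concatenated over pairs is fine).
#' @param truth the `truth` element of a `sim_cohort`.
#' @param traces optional side-level trace data.frame (as
#'   [call_traces_pair()] output) with an added `pair` column and `mosaic`
#'   indexing rows of the per-pair detected mosaic table.
#' @param slack boundary tolerance in bp.
#' @return list with data.frames `mosaics` (n_truth, n_detected, n_matched,
#'   recall, precision) and, when traces are given, `traces` (n_expected,
#'   n_found, recall, n_called, n_called_on_anchor, precision). Precision is
#'   `NA` when nothing was detected/called.
#' @export
score_against_truth <- function(mosaics, truth, traces = NULL, slack = 15L) {
  tm <- truth$mosaics
  n_truth <- nrow(tm); n_det <- nrow(mosaics)
  matched_truth <- rep(NA_integer_, n_truth)  # index of matched detection
  used_det <- rep(FALSE, n_det)
  det_pair <- match(paste(mosaics$g1_id, mosaics$g2_id),
                    paste(truth$pairs$g1_id, truth$pairs$g2_id))
  for (ti in seq_len(n_truth)) {
    cand <- which(!used_det & det_pair == tm$pair[ti])
    for (di in cand) {
      if (.recip_overlap_match(mosaics$g1_start[di], mosaics$g1_end[di],
                               tm$g1_start[ti], tm$g1_end[ti], slack) &&
          .recip_overlap_match(mosaics$g2_start[di], mosaics$g2_end[di],
                               tm$g2_start[ti], tm$g2_end[ti], slack)) {
        matched_truth[ti] <- di
        used_det[di] <- TRUE
        break
      }
    }
  }
  n_matched <- sum(!is.na(matched_truth))
  out <- list(mosaics = data.frame(
    n_truth = n_truth, n_detected = n_det, n_matched = n_matched,
    recall = if (n_truth > 0) n_matched / n_truth else NA_real_,
    precision = if (n_det > 0) sum(used_det) / n_det else NA_real_))

  if (!is.null(traces) && nrow(traces) > 0) {
    # per-pair detection row index for the trace table's `mosaic` column
    det_idx_in_pair <- integer(n_det)
    for (pk in unique(det_pair)) {
      sel <- which(det_pair == pk)
      det_idx_in_pair[sel] <- seq_along(sel)
    }
    tkey <- paste(traces$pair, traces$mosaic, traces$side)
    n_expected <- 0L; n_found <- 0L; n_called <- 0L; n_called_anchor <- 0L
    for (ti in which(!is.na(matched_truth))) {
      di <- matched_truth[ti]
      for (side in c("left", "right")) {
        row <- traces[tkey == paste(tm$pair[ti], det_idx_in_pair[di], side), ,
                      drop = FALSE]
        if (nrow(row) != 1L || !isTRUE(row$testable)) next
        has_anchor <- if (side == "left") tm$anchor_left[ti] else tm$anchor_right[ti]
        masked <- !is.na(tm$masked_side[ti]) && tm$masked_side[ti] == side
        expected <- has_anchor && !masked
        if (expected) {
          n_expected <- n_expected + 1L
          if (isTRUE(row$trace)) n_found <- n_found + 1L
        }
        if (isTRUE(row$trace)) {
          n_called <- n_called + 1L
          if (expected) n_called_anchor <- n_called_anchor + 1L
        }
      }
    }
    out$traces <- data.frame(
      n_expected = n_expected, n_found = n_found,
      recall = if (n_expected > 0) n_found / n_expected else NA_real_,
      n_called = n_called, n_called_on_anchor = n_called_anchor,
      precision = if (n_called > 0) n_called_anchor / n_called else NA_real_)
  }
  out
}
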