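LIFESTYLES <- c("temperate", "defective", "virulent", "unknown")

#' Construct a genome object
#'
#' A genome is an identified DNA sequence over the alphabet A, C, G, T, N,
#' carrying a lifestyle label and, optionally, insertion-sequence (IS)
#' intervals in 0-based half-open coordinates. Sequences are uppercased and
#' characters outside the alphabet are mapped to N.
#'
#' @param id genome identifier (non-empty string).
#' @param seq DNA sequence as a single string.
#' @param lifestyle one of `"temperate"`, `"defective"`, `"virulent"`,
#'   `"unknown"`.
#' @param is_intervals optional two-column matrix or data.frame of 0-based
#'   half-open IS intervals; overlapping intervals are merged.
#' @return An object of class `genome`.
#' @examples
#' g <- genome("g1", "acgtn")
#' g$seq
#' @export
genome <- function(id, seq, lifestyle = "unknown", is_intervals = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L, nzchar(seq))
  lifestyle <- match.arg(lifestyle, LIFESTYLES)
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    warning(sprintf("genome '%s': %d non-ACGTN character(s) mapped to N",
                    id, nchar(bad)))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  iv <- normalize_intervals(is_intervals, nchar(seq), id)
  structure(list(id = id, seq = seq, lifestyle = lifestyle, is_intervals = iv),
            class = "genome")
}

normalize_intervals <- function(iv, len, id) {
  if (is.null(iv) || NROW(iv) == 0L) return(NULL)
  iv <- as.matrix(iv[, 1:2, drop = FALSE])
  storage.mode(iv) <- "integer"
  if (any(iv[, 1] < 0L) || any(iv[, 2] > len) || any(iv[, 1] >= iv[, 2]))
    stop(sprintf("genome '%s': IS intervals out of range", id))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  # merge overlaps
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) for (k in 2:nrow(iv)) {
    if (iv[k, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[k, 2])
    } else out <- rbind(out, iv[k, , drop = FALSE])
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome '%s': %d bp, lifestyle %s, %d IS interval(s)\n",
              x$id, nchar(x$seq), x$lifestyle,
              if (is.null(x$is_intervals)) 0L else nrow(x$is_intervals)))
  invisible(x)
}

.as_genome <- function(x, default_id = "seq") {
  if (inherits(x, "genome")) return(x)
  if (is.character(x) && length(x) == 1L) return(genome(default_id, x))
  stop("expected a genome object or a single DNA string")
}

#' Read genomes from a multi-FASTA file
#'
#' Record ids are the header token before the first whitespace. Sequences are
#' uppercased; characters outside A, C, G, T, N are mapped to N with a
#' warning. Duplicate ids, an empty file, or majority non-nucleotide content
#' raise an error.
#'
#' @param path FASTA file path.
#' @param lifestyles optional named character vector or data.frame with
#'   columns `id` and `lifestyle` used to label the genomes.
#' @return A named list of [genome] objects, in file order.
#' @export
read_genome_fasta <- function(path, lifestyles = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- unname(toupper(as.character(recs)))
  total <- sum(nchar(seqs))
  valid <- sum(nchar(gsub("[^ACGTN]", "", seqs)))
  if (total == 0L || valid / total < 0.5)
    stop("majority non-nucleotide content in ", path)
  if (is.data.frame(lifestyles))
    lifestyles <- stats::setNames(as.character(lifestyles$lifestyle),
                                  as.character(lifestyles$id))
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    ls <- if (!is.null(lifestyles) && ids[k] %in% names(lifestyles))
      lifestyles[[ids[k]]] else "unknown"
    out[[k]] <- genome(ids[k], seqs[k], ls)
  }
  names(out) <- ids
  out
}

#' Write genomes to a multi-FASTA file
#'
#' @param genomes list of [genome] objects.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(genomes, path, width = 70L) {
  con <- file(path, "wb")  # binary mode: byte-stable line endings
  on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$id), con, sep = "\n")
    s <- g$seq
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a lifestyle metadata table
#'
#' Expects a TSV with columns `id` and `lifestyle`.
#'
#' @param path TSV path.
#' @return data.frame with columns `id`, `lifestyle`.
#' @export
read_lifestyle_tsv <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "lifestyle") %in% names(md)))
    stop("metadata must have columns 'id' and 'lifestyle'")
  bad <- setdiff(unique(md$lifestyle), LIFESTYLES)
  if (length(bad)) stop("unknown lifestyle label(s): ", paste(bad, collapse = ", "))
  md[, c("id", "lifestyle")]
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A, C, G, T, N.
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) .revcomp_cpp(toupper(seq))
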