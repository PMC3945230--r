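# shared fixtures and independent oracles, built in code

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# mutate a proportion p of sites, always to a different base
mutate_seq <- function(s, p) {
  v <- match(strsplit(s, "")[[1]], BASES4) - 1L
  hit <- runif(length(v)) < p
  n <- sum(hit)
  if (n) v[hit] <- (v[hit] + sample.int(3L, n, replace = TRUE)) %% 4L
  paste(BASES4[v + 1L], collapse = "")
}

# independent naive Gotoh global alignment score (plain R, full matrices);
# gap of length L costs open + L * extend
naive_global_score <- function(s1, s2, match, mismatch, open, extend) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                   Y[i - 1, j] - open - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, X[i, j - 1] - open - extend,
                   Y[i, j - 1] - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Biostrings-based oracles (independent C implementation)
bs_global_score <- function(s1, s2, sc) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = sc$match,
                                                  mismatch = sc$mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(s1),
                                Biostrings::DNAString(s2),
                                substitutionMatrix = mat,
                                gapOpening = sc$gap_open,
                                gapExtension = sc$gap_extend,
                                type = "global", scoreOnly = TRUE)
}

bs_local_score <- function(s1, s2, sc) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = sc$match,
                                                  mismatch = sc$mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(s1),
                                Biostrings::DNAString(s2),
                                substitutionMatrix = mat,
                                gapOpening = sc$gap_open,
                                gapExtension = sc$gap_extend,
                                type = "local", scoreOnly = TRUE)
}

# ungapped "true" alignment trace rule on two colinear sequences: windows
# anchored at the boundary (column 0), background = median window identity
rule_trace <- function(v1, v2, window_len = 50L, delta = 0.10,
                       proximal_cols = 200L) {
  cols <- ifelse(v1 == v2, 0L, 1L)
  prof <- mosaicscan:::window_cols_profile(cols, window_len)
  b <- median(prof$identity)
  guard <- (b + delta) < 1 - 1 / window_len
  list(b = b,
       trace = guard && any(prof$identity[prof$col_start < proximal_cols] >=
                              b + delta))
}

rand_codes <- function(n) sample(0L:3L, n, replace = TRUE)

mutate_codes_t <- function(v, p) {
  hit <- runif(length(v)) < p
  n <- sum(hit)
  if (n) v[hit] <- (v[hit] + sample.int(3L, n, replace = TRUE)) %% 4L
  v
}

codes_str <- function(v) paste(BASES4[v + 1L], collapse = "")

# substitution probability giving expected pairwise identity b when applied
# independently to both copies of an ancestor
div_for_b <- function(b) (2 - sqrt(4 - (16 / 3) * (1 - b))) / (8 / 3)
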