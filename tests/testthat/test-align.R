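test_that("global alignment handles forced small cases", {
  a <- global_align("ACGTACGTAC", "ACGTACGTAC")
  expect_identical(a$identity, 1)
  expect_identical(a$n_gapcols, 0L)

  a <- global_align("ACGT", "ACGA")
  expect_identical(a$n_match, 3L)
  expect_identical(a$n_mismatch, 1L)
  expect_equal(a$identity, 0.75)

  expect_error(global_align("", "ACGT"), "non-empty")
  expect_error(global_align(strrep("A", 10001), "ACGT"), "chunk")
})

test_that("global alignment score equals two independent DP oracles", {
  set.seed(101)
  sc <- scoring_standard()
  for (k in 1:12) {
    s1 <- rand_seq(sample(30:120, 1))
    s2 <- mutate_seq(s1, 0.2)
    if (k %% 3 == 0) s2 <- rand_seq(sample(30:120, 1))
    mine <- global_align(s1, s2, sc)$score
    expect_identical(mine,
                     naive_global_score(s1, s2, sc$match, sc$mismatch,
                                        sc$gap_open, sc$gap_extend))
    expect_identical(mine, as.numeric(bs_global_score(s1, s2, sc)))
  }
  # relaxed scheme too, at 20% divergence (the flank-realignment regime)
  sc <- scoring_relaxed()
  for (k in 1:5) {
    s1 <- rand_seq(200)
    s2 <- mutate_seq(s1, 0.2)
    expect_identical(global_align(s1, s2, sc)$score,
                     as.numeric(bs_global_score(s1, s2, sc)))
  }
})

test_that("global alignment columns reconstruct the inputs and are reproducible", {
  set.seed(7)
  s1 <- rand_seq(300); s2 <- mutate_seq(s1, 0.3)
  a <- global_align(s1, s2)
  expect_identical(gsub("-", "", a$a1), s1)
  expect_identical(gsub("-", "", a$a2), s2)
  expect_identical(a$n_match + a$n_mismatch + a$n_gapcols, a$length)
  b <- global_align(s1, s2)
  expect_identical(a, b)
})

test_that("self-comparison yields one full-length perfect hit", {
  set.seed(11)
  g <- rand_seq(500)
  h <- find_local_hits(g, g, scoring_standard(), min_len = 100,
                       min_identity = 0.9)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand, "+")
  expect_identical(c(h$g1_start, h$g1_end), c(0L, 500L))
  expect_identical(h$identity, 1)
})

test_that("planted segments are located at the Smith-Waterman optimum", {
  set.seed(23)
  sc <- scoring_standard()
  for (k in 1:8) {
    seg <- rand_seq(300)
    seg2 <- mutate_seq(seg, 0.05)
    realized <- mean(strsplit(seg, "")[[1]] == strsplit(seg2, "")[[1]])
    pos1 <- sample(200:800, 1); pos2 <- sample(200:800, 1)
    s1 <- paste0(rand_seq(pos1), seg, rand_seq(2000 - pos1 - 300))
    s2 <- paste0(rand_seq(pos2), seg2, rand_seq(2000 - pos2 - 300))
    h <- find_local_hits(s1, s2, sc, min_len = 100, min_identity = 0.9)
    expect_identical(nrow(h), 1L)
    expect_lte(abs(h$g1_start - pos1), 15)
    expect_lte(abs(h$g1_end - (pos1 + 300)), 15)
    expect_lte(abs(h$g2_start - pos2), 15)
    # identity within 0.02 of the planted alignment's identity
    expect_lte(abs(h$identity - realized), 0.02)
    # score close to the exhaustive local optimum (trimming can only lose
    # boundary columns; compare untrimmed search to the SW oracle)
    h2 <- find_local_hits(s1, s2, sc, min_len = 100, min_identity = 0.5,
                          trim_identity = 0)
    expect_gte(max(h2$score), 0.95 * bs_local_score(s1, s2, sc))
  }
})

test_that("reverse-complementing g2 flips strands and maps coordinates", {
  set.seed(31)
  seg <- rand_seq(250)
  s1 <- paste0(rand_seq(400), seg, rand_seq(350))
  s2 <- paste0(rand_seq(300), mutate_seq(seg, 0.04), rand_seq(450))
  h_fwd <- find_local_hits(s1, s2, min_len = 100, min_identity = 0.9)
  h_rev <- find_local_hits(s1, revcomp(s2), min_len = 100, min_identity = 0.9)
  expect_identical(nrow(h_fwd), nrow(h_rev))
  expect_identical(h_fwd$score, h_rev$score)
  expect_true(all(h_fwd$strand != h_rev$strand))
  L <- nchar(s2)
  expect_identical(h_rev$g2_start, L - h_fwd$g2_end)
  expect_identical(h_rev$g2_end, L - h_fwd$g2_start)
})

test_that("unrelated sequences yield no high-identity hits", {
  set.seed(37)
  h <- find_local_hits(rand_seq(3000), rand_seq(3000),
                       min_len = 100, min_identity = 0.9)
  expect_identical(nrow(h), 0L)
})

test_that("window profile matches a brute-force recount", {
  # forced cases
  a <- list(a1 = strrep("A", 100), a2 = strrep("A", 100))
  p <- window_profile(a, 50)
  expect_equal(p$identity, c(1, 1))
  v <- rep("A", 100); v[seq(5, 100, by = 5)] <- "C"
  p <- window_profile(list(a1 = strrep("A", 100), a2 = paste(v, collapse = "")), 50)
  expect_equal(p$identity, c(0.8, 0.8))
  # random alignment vs direct recount, and window conservation
  set.seed(41)
  s1 <- rand_seq(740); s2 <- mutate_seq(s1, 0.25)
  aln <- global_align(s1, s2)
  p <- window_profile(aln, 50)
  cols <- mosaicscan:::.aln_columns_cpp(aln$a1, aln$a2)
  n_win <- length(cols) %/% 50
  for (w in seq_len(n_win)) {
    manual <- mean(cols[((w - 1) * 50 + 1):(w * 50)] == 0L)
    expect_equal(p$identity[w], manual)
  }
  trunc_match <- sum(cols[seq_len(n_win * 50)] == 0L)
  expect_equal(sum(p$identity) * 50, trunc_match)
  expect_error(window_profile(list(a1 = "ACGT", a2 = "ACGT"), 50), "window")
})
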