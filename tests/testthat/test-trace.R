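# builds one synthetic pair with a single mid-genome mosaic and chosen
# anchors; returns genomes plus the detected mosaic row
make_anchored_pair <- function(b = 0.60, glen = 12000L, mstart = 5500L,
                               mlen = 400L, anchor_len = 200L,
                               anchor_id = b + 0.20,
                               left = TRUE, right = TRUE) {
  p <- div_for_b(b)
  anc <- rand_codes(glen)
  v1 <- mutate_codes_t(anc, p); v2 <- mutate_codes_t(anc, p)
  idx <- (mstart + 1L):(mstart + mlen)
  v2[idx] <- mutate_codes_t(v1[idx], 0.03)
  if (left) {
    ai <- (mstart - anchor_len + 1L):mstart
    v2[ai] <- mutate_codes_t(v1[ai], 1 - anchor_id)
  }
  if (right) {
    ai <- (mstart + mlen + 1L):(mstart + mlen + anchor_len)
    v2[ai] <- mutate_codes_t(v1[ai], 1 - anchor_id)
  }
  g1 <- genome("gA", codes_str(v1)); g2 <- genome("gB", codes_str(v2))
  det <- detect_mosaics(g1, g2)
  list(g1 = g1, g2 = g2, det = det)
}

test_that("flank extraction respects boundaries, truncation and strand", {
  set.seed(201)
  g1 <- genome("a", rand_seq(30000)); g2 <- genome("b", rand_seq(30000))
  mid <- data.frame(g1_start = 15000L, g1_end = 15400L,
                    g2_start = 9000L, g2_end = 9400L, strand = "+")
  fl <- extract_flanks(mid, g1, g2)
  expect_identical(nchar(fl$left$s1), 2000L)
  expect_identical(nchar(fl$right$s2), 2000L)
  expect_false(fl$left$truncated)
  expect_identical(fl$left$s1, substr(g1$seq, 13001, 15000))
  expect_identical(fl$right$s2, substr(g2$seq, 9401, 11400))

  # mosaic at genome start: left flank empty and untestable
  edge <- data.frame(g1_start = 0L, g1_end = 300L,
                     g2_start = 100L, g2_end = 400L, strand = "+")
  fl <- extract_flanks(edge, g1, g2)
  expect_identical(nchar(fl$left$s1), 0L)
  expect_true(fl$left$truncated)
  expect_false(fl$left$testable)

  # minus strand: flanks are reverse complements of independent slicing
  neg <- data.frame(g1_start = 15000L, g1_end = 15400L,
                    g2_start = 9000L, g2_end = 9400L, strand = "-")
  fl <- extract_flanks(neg, g1, g2)
  expect_identical(fl$left$s2, revcomp(substr(g2$seq, 9401, 11400)))
  expect_identical(fl$right$s2, revcomp(substr(g2$seq, 7001, 9000)))
  expect_identical(fl$left$s1, substr(g1$seq, 13001, 15000))
})

test_that("planted anchors drive per-side trace calls", {
  set.seed(203)
  pr <- make_anchored_pair(left = TRUE, right = FALSE)
  expect_identical(nrow(pr$det), 1L)
  tc <- call_traces(pr$det[1, ], pr$g1, pr$g2)
  expect_true(tc$left$trace)
  expect_identical(tc$n_testable_sides, 2L)

  pr2 <- make_anchored_pair(left = TRUE, right = TRUE)
  tc2 <- call_traces(pr2$det[1, ], pr2$g1, pr2$g2)
  expect_identical(tc2$n_traces, 2L)

  # trace calls are deterministic
  tc3 <- call_traces(pr2$det[1, ], pr2$g1, pr2$g2)
  expect_identical(tc2, tc3)
})

test_that("masking one anchor removes its trace but not the other side's", {
  set.seed(207)
  masked_rate <- 0; unmasked_rate <- 0
  n <- 15
  for (k in 1:n) {
    pr <- make_anchored_pair(left = TRUE, right = TRUE)
    # overwrite the left anchor on g2 with unrelated sequence (a later
    # exchange with a third genome)
    m <- pr$det[1, ]
    v2 <- match(strsplit(pr$g2$seq, "")[[1]], BASES4) - 1L
    ai <- (m$g2_start - 200L + 1L):m$g2_start
    v2[ai] <- rand_codes(200L)
    g2m <- genome("gB", codes_str(v2))
    tc <- call_traces(m, pr$g1, g2m)
    masked_rate <- masked_rate + tc$left$trace
    unmasked_rate <- unmasked_rate + tc$right$trace
  }
  expect_gte(unmasked_rate / n, 0.9)
  expect_lte(masked_rate / n, 0.5)
})

test_that("the binomial null equals a brute-force tail sum and its guards hold", {
  # threshold above 1: probability exactly 0
  expect_identical(random_trace_probability(0.95, 4, 10), 0)
  # exact tail-sum oracle at b = 0.60, one window, one side
  b <- 0.60; W <- 50L; k <- ceiling(W * (b + 0.10))
  tail_sum <- sum(vapply(k:W, function(x)
    choose(W, x) * b^x * (1 - b)^(W - x), 0))
  expect_equal(random_trace_probability(b, 1, 1), tail_sum, tolerance = 1e-12)
  # aggregation over independent windows
  q <- tail_sum
  expect_equal(random_trace_probability(b, 4, 6), 1 - (1 - q)^24,
               tolerance = 1e-12)
})

test_that("permutation and binomial nulls agree on indel-free alignments", {
  set.seed(211)
  b <- 0.60
  cols <- ifelse(runif(2000) < b, 0L, 1L)
  b_emp <- mean(cols == 0L)
  p_bin <- random_trace_probability(b_emp, 4, 1)
  n_perm <- 600L
  p_perm <- random_trace_probability(b_emp, 4, 1, method = "permutation",
                                     match_cols = cols, n_perm = n_perm,
                                     seed = 212)
  se <- sqrt(p_bin * (1 - p_bin) / n_perm)
  expect_lt(abs(p_perm - p_bin), 3 * se + 0.02)
})

test_that("trace fractions aggregate per mosaic", {
  z <- data.frame(mosaic = rep(1:4, each = 2), side = rep(c("left", "right"), 4),
                  n_traces = 0L, n_testable_sides = 2L)
  expect_equal(trace_fraction(z), 0)
  # the printed category breakdown: 432 / 169 / 34 mosaics by trace count
  counts <- c(rep(0L, 432), rep(1L, 169), rep(2L, 34))
  tab <- data.frame(mosaic = seq_along(counts), n_traces = counts,
                    n_testable_sides = 2L)
  expect_equal(round(trace_fraction(tab), 0), 32)
  expect_true(abs(trace_fraction(tab) - 100 * (169 + 34) / 635) < 1e-9)
})

test_that("planted anchor prevalence is recovered up to the measured null rate", {
  set.seed(219)
  n <- 40; p_anchor <- 0.4
  planted <- runif(n) < p_anchor
  called_left <- logical(n); called_right <- logical(n)
  p_bg <- div_for_b(0.6)
  for (k in 1:n) {
    anc <- rand_codes(2000)
    v1 <- mutate_codes_t(anc, p_bg); v2 <- mutate_codes_t(anc, p_bg)
    if (planted[k]) v2[1:200] <- mutate_codes_t(v1[1:200], 0.2)
    r <- rule_trace(v1, v2)
    called_left[k] <- r$trace
    anc <- rand_codes(2000)
    w1 <- mutate_codes_t(anc, p_bg); w2 <- mutate_codes_t(anc, p_bg)
    called_right[k] <- rule_trace(w1, w2)$trace
  }
  fp <- random_trace_probability(0.6, 4, 1)
  expected <- 100 * (1 - (1 - (p_anchor + (1 - p_anchor) * fp)) * (1 - fp))
  got <- 100 * mean(called_left | called_right)
  # binomial sd of the estimate, plus null-model slack
  sd_est <- 100 * sqrt(expected / 100 * (1 - expected / 100) / n)
  expect_lt(abs(got - expected), 3 * sd_est + 5)
})
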