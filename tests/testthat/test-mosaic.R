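test_that("identical genomes give one genome-spanning mosaic", {
  set.seed(71)
  g <- rand_seq(10000)
  m <- detect_mosaics(g, g)
  expect_identical(nrow(m), 1L)
  expect_identical(c(m$g1_start, m$g1_end), c(0L, 10000L))
  expect_identical(m$identity, 1)
})

test_that("planted mosaics at 60% background are recovered within 15 bp", {
  set.seed(73)
  p <- div_for_b(0.60)
  anc <- rand_codes(30000)
  v1 <- mutate_codes_t(anc, p); v2 <- mutate_codes_t(anc, p)
  plant <- data.frame(start = c(3000L, 12000L, 22000L),
                      len = c(150L, 400L, 800L),
                      id = c(0.95, 0.97, 0.99))
  for (k in 1:3) {
    idx <- (plant$start[k] + 1L):(plant$start[k] + plant$len[k])
    v2[idx] <- mutate_codes_t(v1[idx], 1 - plant$id[k])
  }
  m <- detect_mosaics(codes_str(v1), codes_str(v2))
  expect_identical(nrow(m), 3L)
  expect_true(all(abs(m$g1_start - plant$start) <= 15))
  expect_true(all(abs(m$g1_end - (plant$start + plant$len)) <= 15))
  expect_true(all(m$identity > 0.90 & m$length >= 100))
})

test_that("unrelated genomes yield no mosaics", {
  set.seed(79)
  m <- detect_mosaics(rand_seq(20000), rand_seq(20000))
  expect_identical(nrow(m), 0L)
})

test_that("IS filtering removes shared repeats and partitions the set", {
  set.seed(83)
  co <- simulate_cohort(sim_config(seed = 83, n_pairs = 1, genome_len = 30000,
                                   n_mosaics = 2, n_is = 2))
  g1 <- co$genomes[[1]]; g2 <- co$genomes[[2]]
  det <- detect_mosaics(g1, g2)
  expect_gte(nrow(det), 4L)  # 2 mosaics + 2 IS-vs-IS pairs at least

  # empty catalog: everything kept
  fi0 <- filter_is(det, list(g1, g2),
                   data.frame(genome_id = character(0), start = integer(0),
                              end = integer(0)))
  expect_identical(nrow(fi0$kept), nrow(det))
  expect_identical(fi0$pct_is, 0)

  # FASTA catalog route: IS-derived hits removed
  fi <- filter_is(det, list(g1, g2), co$is_catalog)
  expect_identical(nrow(fi$kept) + nrow(fi$removed), nrow(det))
  expect_equal(fi$pct_is, 100 * nrow(fi$removed) / nrow(det))
  expect_gte(nrow(fi$removed), 2L)
  # all planted mosaics survive the filter
  sc <- score_against_truth(fi$kept, co$truth)
  expect_identical(sc$mosaics$n_matched, 2L)

  # intervals route via the genomes' own annotations agrees
  fi2 <- filter_is(det, list(g1, g2), NULL)
  expect_identical(nrow(fi2$removed), nrow(fi$removed))

  # a mosaic overlapping an IS by only 10% is kept
  fake <- det[1, ]
  fake$g1_start <- 1000L; fake$g1_end <- 2000L
  fake$g2_start <- 1000L; fake$g2_end <- 2000L
  iv <- data.frame(genome_id = c(g1$id, g2$id),
                   start = c(1900L, 1900L), end = c(3000L, 3000L))
  fi3 <- filter_is(fake, list(g1, g2), iv)
  expect_identical(nrow(fi3$kept), 1L)
  expect_equal(fi3$kept$is_overlap, 0.1)
})

test_that("mosaic density follows its definition", {
  set.seed(89)
  g1 <- rand_seq(40000); g2 <- rand_seq(40000)
  m0 <- data.frame()
  expect_identical(mosaic_density(m0, g1, g2), 0)
  m2 <- data.frame(g1_start = c(1, 2))  # only the row count matters
  expect_identical(mosaic_density(m2, g1, g2), 0.5)
  # recount oracle over a simulated pair
  co <- simulate_cohort(sim_config(seed = 90, n_pairs = 1, genome_len = 20000,
                                   n_mosaics = 2))
  det <- detect_mosaics(co$genomes[[1]], co$genomes[[2]])
  expect_equal(mosaic_density(det, co$genomes[[1]], co$genomes[[2]]),
               nrow(det) / (20000 / 10000))
})

test_that("category summaries report planted counts and single-element medians", {
  pair_tab <- data.frame(pair = 1:2, g1_id = c("a", "c"), g2_id = c("b", "d"),
                         lifestyle1 = c("temperate", "temperate"),
                         lifestyle2 = c("temperate", "defective"),
                         category = c("T-T", "T-D"),
                         ani = NA, coverage = NA,
                         status = "analyzed",
                         n_blast_matches = c(3L, 1L), n_is_removed = c(1L, 0L),
                         n_mosaics = c(2L, 1L), density = NA, mean_traces = NA)
  mosaics <- data.frame(pair = c(1L, 1L, 2L),
                        length = c(300L, 500L, 404L),
                        identity = c(0.95, 0.99, 0.961),
                        n_traces = c(0L, 1L, 2L),
                        n_testable_sides = c(2L, 2L, 2L))
  traces <- data.frame(pair = c(1L, 1L, 1L, 1L, 2L, 2L),
                       mosaic = c(1L, 1L, 2L, 2L, 1L, 1L),
                       b = 0.6)
  cs <- summarize_categories(pair_tab, mosaics, traces)
  expect_identical(cs$category, c("T-T", "T-D", "D-D", "V-V", "V-other"))
  tt <- cs[cs$category == "T-T", ]
  expect_identical(tt$n_mosaics, 2L)
  expect_equal(tt$mosaics_per_pair, 2)
  expect_equal(tt$median_len, 400)
  expect_equal(tt$pct_is, 100 / 3)
  td <- cs[cs$category == "T-D", ]
  expect_equal(td$median_len, 404)
  expect_equal(td$median_id, 96.1)
  expect_identical(td$n_two_trace, 1L)
  expect_identical(cs$n_pairs[cs$category == "V-V"], 0L)
  # trace-count breakdown partitions m
  expect_true(all(cs$n_zero_trace + cs$n_one_trace + cs$n_two_trace ==
                    cs$n_mosaics))
})
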