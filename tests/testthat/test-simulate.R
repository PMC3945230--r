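test_that("identical seeds give byte-identical cohorts", {
  cfg <- sim_config(seed = 42, n_pairs = 2, genome_len = 15000, n_mosaics = 2,
                    n_is = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in c("genomes.fasta", "metadata.tsv", "truth_mosaics.tsv",
              "truth_anchors.tsv", "truth_is.tsv", "is_catalog.fasta")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the sequences
  cfg2 <- sim_config(seed = 43, n_pairs = 2, genome_len = 15000,
                     n_mosaics = 2, n_is = 1)
  d3 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genomes.fasta"))),
                         unname(tools::md5sum(file.path(d3, "genomes.fasta")))))
})

test_that("planted counts and identities match the configuration", {
  co <- simulate_cohort(sim_config(seed = 7, n_pairs = 10, genome_len = 20000,
                                   n_mosaics = 3))
  expect_identical(nrow(co$truth$mosaics), 30L)
  expect_true(all(co$truth$mosaics$identity >= 0.90))
  expect_true(all(co$truth$mosaics$length >= 150 &
                    co$truth$mosaics$length <= 800))
  # anchors abut the mosaic boundaries
  an <- merge(co$truth$anchors, co$truth$mosaics,
              by = c("pair", "mosaic"), suffixes = c("", ".m"))
  left <- an[an$side == "left", ]
  right <- an[an$side == "right", ]
  expect_true(all(left$g1_end == left$g1_start.m))
  expect_true(all(right$g1_start == right$g1_end.m))
})

test_that("background identity of generated pairs is within one point of b", {
  co <- simulate_cohort(sim_config(seed = 9, n_pairs = 5, genome_len = 20000,
                                   n_mosaics = 0))
  for (pk in 1:5) {
    s1 <- strsplit(co$genomes[[2 * pk - 1]]$seq, "")[[1]]
    s2 <- strsplit(co$genomes[[2 * pk]]$seq, "")[[1]]
    expect_lt(abs(mean(s1 == s2) - 0.60), 0.01)
  }
  expect_true(all(abs(co$truth$pairs$background - 0.60) < 0.01))
})

test_that("a mosaic-free cohort yields no detections", {
  co <- simulate_cohort(sim_config(seed = 15, n_pairs = 1, genome_len = 20000,
                                   n_mosaics = 0))
  det <- detect_mosaics(co$genomes[[1]], co$genomes[[2]])
  expect_identical(nrow(det), 0L)
})

test_that("scoring against truth behaves at the extremes", {
  co <- simulate_cohort(sim_config(seed = 21, n_pairs = 2, genome_len = 20000,
                                   n_mosaics = 2))
  tm <- co$truth$mosaics
  perfect <- data.frame(g1_id = tm$g1_id, g2_id = tm$g2_id,
                        g1_start = tm$g1_start, g1_end = tm$g1_end,
                        g2_start = tm$g2_start, g2_end = tm$g2_end)
  sc <- score_against_truth(perfect, co$truth)
  expect_equal(sc$mosaics$recall, 1)
  expect_equal(sc$mosaics$precision, 1)

  empty <- perfect[0, ]
  sc0 <- score_against_truth(empty, co$truth)
  expect_equal(sc0$mosaics$recall, 0)
  expect_true(is.na(sc0$mosaics$precision))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(genome_len = 6000, n_mosaics = 3), "infeasible")
  expect_error(sim_config(background_identity = 0.2), "background_identity")
})

test_that("masking shifts planted anchors from two traces to one in truth", {
  co <- simulate_cohort(sim_config(seed = 33, n_pairs = 6, genome_len = 20000,
                                   n_mosaics = 2, p_anchor_left = 1,
                                   p_anchor_right = 1, p_mask = 1))
  expect_true(all(!is.na(co$truth$mosaics$masked_side)))
  expect_identical(sum(co$truth$anchors$masked), nrow(co$truth$mosaics))
})
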