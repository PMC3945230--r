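test_that("ANI of a genome with itself is 100/100", {
  set.seed(51)
  g <- rand_seq(5000)
  a <- ani_coverage(g, g)
  expect_equal(a$ani, 100)
  expect_equal(a$coverage, 100)
  expect_identical(a$n_contributing, a$n_fragments)
})

test_that("ANI tracks simulated per-site divergence and is near-symmetric", {
  set.seed(53)
  anc <- rand_codes(20000)
  s1 <- codes_str(anc)
  s2 <- codes_str(mutate_codes_t(anc, 0.15))
  a12 <- ani_coverage(s1, s2)
  # 15% per-site substitution, no indels: ANI in [83, 87]
  expect_gte(a12$ani, 83)
  expect_lte(a12$ani, 87)
  expect_equal(a12$coverage, 100)
  a21 <- ani_coverage(s2, s1)
  expect_lt(abs(a12$ani - a21$ani), 2)
})

test_that("expected ANI decreases with divergence", {
  set.seed(57)
  mean_ani <- vapply(c(0, 0.05, 0.10, 0.20, 0.30), function(d) {
    mean(vapply(1:5, function(r) {
      anc <- rand_codes(6000)
      ani_coverage(codes_str(anc), codes_str(mutate_codes_t(anc, d)))$ani
    }, 0))
  }, 0)
  expect_true(all(diff(mean_ani) < 0))
})

test_that("unrelated genomes have near-zero ANI coverage", {
  set.seed(59)
  a <- ani_coverage(rand_seq(15000), rand_seq(15000))
  expect_lt(a$coverage, 10)
})

test_that("pair classification applies the printed thresholds", {
  gs <- list(genome("a", strrep("ACGT", 10), "temperate"),
             genome("b", strrep("ACGT", 10), "temperate"),
             genome("c", strrep("ACGT", 10), "virulent"),
             genome("d", strrep("ACGT", 10), "virulent"))
  names(gs) <- vapply(gs, function(g) g$id, "")
  ani <- data.frame(
    g1_id = c("a", "a", "c", "a", "b"),
    g2_id = c("b", "c", "d", "d", "c"),
    ani = c(95, 71, 69, 69, 50),
    coverage = c(90, 51, 47, 47, 20))
  cls <- classify_pairs(gs, ani)
  expect_identical(cls$status[1], "redundant")       # 95/90
  expect_identical(attr(cls, "dropped"), "b")        # lexicographically larger
  expect_identical(cls$status[2], "excluded_related") # temperate 71/51
  expect_identical(cls$status[3], "analyzed")        # virulent 69/47
  expect_identical(cls$status[4], "analyzed")        # mixed below 70/50
  expect_identical(cls$status[5], "analyzed")

  # virulent pair just over its own bounds is excluded
  ani2 <- data.frame(g1_id = "c", g2_id = "d", ani = 68.5, coverage = 48.5)
  expect_identical(classify_pairs(gs, ani2)$status, "excluded_related")
  expect_error(classify_pairs(gs["a"], ani), "absent")
})

test_that("homology-region screen finds planted regions, none after shuffling", {
  set.seed(61)
  region <- rand_seq(800)
  phage <- paste0(rand_seq(1000), region, rand_seq(1200))
  host <- paste0(rand_seq(2000), mutate_seq(region, 0.15), rand_seq(3000))
  hr <- find_homology_regions(phage, host)
  expect_gte(nrow(hr), 1L)
  expect_true(any(hr$length >= 500 & hr$identity > 0.8))
  # column-shuffle null: same composition, no homology
  for (k in 1:10) {
    shuf <- paste(sample(strsplit(host, "")[[1]]), collapse = "")
    expect_identical(nrow(find_homology_regions(phage, shuf)), 0L)
  }
})
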