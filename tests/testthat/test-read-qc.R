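test_that("trim_sliding keeps the longest passing segment", {
  # spec-style example: Q25, window 2
  qual <- c(30L, 30L, 30L, 2L, 30L, 30L, 30L, 30L, 30L)
  seq <- strrep("A", 9)
  t <- trim_sliding(seq, qual, 25, 2)
  expect_equal(c(t$start, t$end), c(5L, 9L))
  expect_equal(t$seq, strrep("A", 5))
  # and it equals the exhaustive-substring oracle
  o <- oracle_trim_longest(qual, 25, 2)
  expect_equal(c(t$start, t$end), unname(o))
})

test_that("trim_sliding first_fail mode keeps only the passing prefix", {
  qual <- c(30L, 30L, 30L, 2L, 30L, 30L, 30L, 30L, 30L)
  t <- trim_sliding(strrep("A", 9), qual, 25, 2, mode = "first_fail")
  expect_equal(c(t$start, t$end), c(1L, 3L))
  # read starting under threshold is dropped entirely
  t2 <- trim_sliding(strrep("A", 5), c(2L, 2L, 30L, 30L, 30L), 25, 2,
                     mode = "first_fail")
  expect_equal(t2$seq, "")
})

test_that("trimming output length is monotone in the quality threshold", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(40:80, 1)
    qual <- rand_quals(n)
    seq <- rand_dna(n)
    for (w in c(5L, 2L)) {
      lens <- vapply(c(20, 25, 30), function(q) {
        nchar(trim_sliding(seq, qual, q, w)$seq)
      }, numeric(1))
      expect_true(all(diff(lens) <= 0))
      expect_lte(lens[1], n) # never longer than raw
    }
  }
})

test_that("filter_read distinguishes short and ambiguous reads", {
  expect_equal(filter_read("ACGT", min_len = 10)$reason, "short")
  expect_equal(filter_read(paste0(strrep("A", 20), "N"),
                           min_len = 10)$reason, "ambiguous")
  expect_true(filter_read(strrep("ACGT", 60))$keep)
})

test_that("merge_pairs emits the higher-quality base on conflicts", {
  set.seed(32)
  core <- rand_dna(120)
  fwd_seq <- substr(core, 1, 80)
  rev_tpl <- substring(core, 31) # overlap 50
  # plant one mismatch in the overlap, at core position 60 (fwd pos 60)
  fwd_mut <- mutate_at(fwd_seq, 60)
  fwd_qual <- rep(30L, 80)
  rev_qual <- rep(35L, 90)
  m <- merge_pairs(fwd_mut, fwd_qual, revcomp(rev_tpl), rev(rev_qual))
  expect_true(m$merged)
  expect_equal(m$overlap, 50L)
  # the reverse mate wins the conflicting base: the merged sequence is core
  expect_equal(m$seq, core)
  expect_equal(m$qual[60], 35L - 30L)
  # agreement takes the max quality
  expect_equal(m$qual[61], 35L)
  # and the whole result matches the all-offsets oracle
  o <- oracle_merge(fwd_mut, fwd_qual, revcomp(rev_tpl), rev(rev_qual))
  expect_equal(m$seq, o$seq)
  expect_equal(m$qual, o$qual)
  expect_equal(m$overlap, o$overlap)
})

test_that("merge_pairs rejects non-overlapping and divergent pairs", {
  set.seed(33)
  a <- rand_dna(60)
  b <- rand_dna(60)
  m <- merge_pairs(a, rep(30L, 60), b, rep(30L, 60))
  expect_false(m$merged)
  expect_equal(m$reason, "too_divergent")
  m2 <- merge_pairs(substr(a, 1, 10), rep(30L, 10), b, rep(30L, 60))
  expect_false(m2$merged)
  expect_equal(m2$reason, "no_overlap")
})

test_that("qc_library trims, filters and merges coherently", {
  set.seed(34)
  core <- rand_dna(253)
  fwd <- read_set(c("r1", "r2"),
                  c(substr(core, 1, 250), substr(core, 1, 250)),
                  list(rep(38L, 250), c(rep(38L, 150), rep(5L, 100))))
  rev <- read_set(c("r1", "r2"),
                  rep(revcomp(substring(core, 4)), 2),
                  list(rep(35L, 250), rep(35L, 250)))
  qc <- qc_library(fwd, rev, "Q30-W5", min_len = 200L)
  # r2's forward mate collapses below 200 bases and the pair is dropped
  expect_equal(qc$fwd$id, "r1")
  expect_equal(length(qc$merged), 1L)
  expect_equal(qc$merged$seq, core)
  expect_equal(qc$summary$pairs_dropped, 1L)
})
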