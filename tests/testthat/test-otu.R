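test_that("dereplicate counts and orders uniques", {
  seqs <- c("AAA", "CCC", "AAA", "TTT", "CCC", "AAA")
  u <- dereplicate(seqs)
  expect_equal(u$seq, c("AAA", "CCC", "TTT"))
  expect_equal(u$abundance, c(3L, 2L, 1L))
  # abundance ties break lexicographically
  u2 <- dereplicate(c("GGG", "AAA"))
  expect_equal(u2$seq, c("AAA", "GGG"))
  # random multiset matches brute-force counting
  set.seed(61)
  pool <- sample(c("ACGT", "TTAA", "GGCC", "ATAT"), 50, replace = TRUE)
  u3 <- dereplicate(pool)
  for (i in seq_len(nrow(u3))) {
    expect_equal(u3$abundance[i], sum(pool == u3$seq[i]))
  }
  expect_true(all(diff(u3$abundance) <= 0))
})

test_that("rarefy subsamples reproducibly and rejects short libraries", {
  x <- 1:100
  a <- rarefy(x, depth = 30L, seed = 5L)
  b <- rarefy(x, depth = 30L, seed = 5L)
  expect_identical(a, b)
  expect_equal(length(a), 30L)
  expect_true(all(a %in% x))
  expect_false(anyDuplicated(a) > 0)
  expect_error(rarefy(1:10, depth = 11L, library_id = "libZ"), "libZ")
})

test_that("cluster_greedy applies both radius conditions conjunctively", {
  set.seed(62)
  base <- rand_dna(253)
  near <- mutate_seq(base, 5L) # within 97% and <= 7 errors
  far <- mutate_seq(base, 20L) # outside both
  u <- data.frame(seq = c(base, near, far),
                  abundance = c(10L, 5L, 2L), stringsAsFactors = FALSE)
  cl <- cluster_greedy(u)
  expect_equal(cl$centroid, c(1L, 1L, 2L))
  expect_equal(cl$otus$representative, c(base, far))
  # identity is normalised by query length: a clean fragment contained in
  # the centroid joins it, while a centroid-length read whose tail hangs
  # off a short centroid is split by the overhang errors
  frag <- substr(base, 1, 150)
  u2 <- data.frame(seq = c(base, frag), abundance = c(3L, 1L))
  expect_equal(cluster_greedy(u2)$centroid, c(1L, 1L))
  u3 <- data.frame(seq = c(frag, base), abundance = c(3L, 1L))
  expect_equal(cluster_greedy(u3)$centroid, c(1L, 2L))
})

test_that("the k-mer screen does not change the greedy partition", {
  set.seed(63)
  bases <- vapply(1:4, function(i) rand_dna(80), character(1))
  seqs <- vapply(1:30, function(i) {
    mutate_seq(bases[sample(4, 1)], sample(0:4, 1))
  }, character(1))
  u <- dereplicate(seqs)
  cl <- cluster_greedy(u, identity_threshold = 0.95, max_errors = 5L)
  oracle <- oracle_first_fit(u, identity_threshold = 0.95, max_errors = 5L)
  expect_equal(cl$centroid, oracle)
})

test_that("build_otu_table sums members per library", {
  set.seed(64)
  base <- rand_dna(100)
  other <- rand_dna(100)
  seqs <- c(base, base, mutate_seq(base, 1L), other, other)
  libs <- c("L1", "L1", "L2", "L1", "L2")
  ot <- build_otu_table(seqs, libs)
  expect_equal(dim(ot$counts), c(2L, 2L))
  expect_equal(sum(ot$counts), 5L)
  expect_equal(unname(colSums(ot$counts)), c(3L, 2L))
  expect_equal(length(ot$read_otu), 5L)
  # the two 'other' reads share one OTU across both libraries
  o2 <- ot$read_otu[4]
  expect_equal(ot$read_otu[5], o2)
  expect_equal(unname(ot$counts[o2, ]), c(1L, 1L))
})

test_that("flag_unique_otus classifies by replicate presence and count", {
  counts <- rbind(
    OTU1 = c(L1 = 5L, L2 = 4L), # shared
    OTU2 = c(L1 = 1L, L2 = 0L), # singleton
    OTU3 = c(L1 = 2L, L2 = 0L), # doubleton
    OTU4 = c(L1 = 4L, L2 = 0L) # other_unique
  )
  ot <- structure(list(counts = counts), class = "otu_table")
  ot <- flag_unique_otus(ot)
  expect_equal(unname(ot$flags),
               c("shared", "singleton", "doubleton", "other_unique"))
  # two libraries mapped to one replicate: presence in both is still unique
  ot2 <- structure(list(counts = counts), class = "otu_table")
  ot2 <- flag_unique_otus(ot2, replicate_map = c(L1 = "A", L2 = "A"))
  expect_equal(unname(ot2$flags[1]), "other_unique")
})

test_that("classify_artifacts follows the decision order", {
  panel <- make_panel()
  refs <- panel_refs(panel)
  cont <- synth_contaminants(n = 2L)
  db <- synth_external_db(panel, contaminants = cont)
  set.seed(65)
  s1 <- names(refs)[1]
  reps <- c(
    true = mutate_seq(refs[[s1]], 2L), # >= 97% to a strain
    chim = paste0(substr(refs[[3]], 1, 130), substring(refs[[8]], 131)),
    cont = unname(cont[1]), # in db, far from mock
    err = mutate_seq(refs[[5]], 30L), # ~88% to mock: erroneous
    junk = rand_dna(253) # matches nothing
  )
  ot <- structure(list(
    otus = data.frame(otu_id = paste0("OTU", 1:5),
                      representative = unname(reps),
                      stringsAsFactors = FALSE),
    counts = matrix(1L, 5, 1, dimnames = list(paste0("OTU", 1:5), "L1")),
    read_otu = paste0("OTU", 1:5)
  ), class = "otu_table")
  ot <- classify_artifacts(ot, refs, db)
  cls <- unname(ot$classification)
  expect_equal(cls[1], paste0("true_strain:", s1))
  expect_equal(cls[2], "chimera")
  expect_equal(cls[3], "contaminant")
  expect_equal(cls[4], "erroneous")
  expect_equal(cls[5], "contaminant_lowconf")
})

test_that("unique_otu_summary cross-tabulates flags and classes", {
  ot <- structure(list(
    flags = c(OTU1 = "shared", OTU2 = "singleton"),
    classification = c(OTU1 = "true_strain:S1", OTU2 = "chimera")
  ), class = "otu_table")
  tab <- unique_otu_summary(ot)
  expect_equal(tab["shared", "true_strain"], 1L)
  expect_equal(tab["singleton", "chimera"], 1L)
})
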