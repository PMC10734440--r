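test_that("extract_v4 cuts the insert between the primer sites", {
  set.seed(11)
  insert <- rand_dna(253)
  full <- paste0(rand_dna(30), "GTGCCAGCAGCCGCGGTAA", insert,
                 revcomp("GGACTACTAGGGTATCTAAT"), rand_dna(30))
  res <- extract_v4(full)
  expect_equal(res$status, "ok")
  expect_equal(res$v4, insert)
  expect_equal(res$fwd_mm, 0L)
  expect_equal(res$rev_mm, 0L)
})

test_that("extract_v4 flags primer mismatches and missing sites", {
  set.seed(12)
  insert <- rand_dna(100)
  fwd_site <- "GTGCCAGCAGCCGCGGTAA"
  # three substitutions in the forward site: beyond max_mismatch = 2
  bad_fwd <- mutate_at(fwd_site, c(3, 8, 15))
  full <- paste0(rand_dna(20), bad_fwd, insert,
                 revcomp("GGACTACTAGGGTATCTAAT"), rand_dna(20))
  res <- extract_v4(full)
  expect_equal(res$status, "primer_mismatch")
  expect_true(is.na(res$v4))
  expect_equal(res$fwd_mm, 3L)
  # no sites at all
  res2 <- extract_v4(rand_dna(80))
  expect_equal(res2$status, "no_site")
})

test_that("flagged strains stay in the table with a recovered insert", {
  set.seed(13)
  insert <- rand_dna(100)
  bad_fwd <- mutate_at("GTGCCAGCAGCCGCGGTAA", c(3, 8, 15))
  full <- paste0(rand_dna(20), bad_fwd, insert,
                 revcomp("GGACTACTAGGGTATCTAAT"), rand_dna(20))
  st <- strain_table("S1", full)
  st <- extract_v4_all(st)
  expect_false(st$amplifiable[1])
  expect_equal(st$v4_seq[1], insert) # recovered despite the flag
  expect_equal(st$primer_mismatches_fwd[1], 3L)
})

test_that("assign_gc_clusters ranks into thirds with overrides", {
  gc <- c(30, 40, 50, 60, 70, 80)
  st <- strain_table(paste0("S", 1:6), rep(strrep("A", 10), 6))
  st$gc_percent <- gc
  st$v4_seq <- strrep("A", 10)
  cl <- assign_gc_clusters(st)
  expect_equal(cl$gc_cluster, c("low", "low", "medium", "medium",
                                "high", "high"))
  cl2 <- assign_gc_clusters(st, overrides = c(S1 = "high"))
  expect_equal(cl2$gc_cluster[1], "high")
  expect_error(assign_gc_clusters(st[1:4, ]), "divisible by 3")
})

test_that("build_design validates tier maps and writes round-trippable TSVs", {
  st <- make_panel()
  d2 <- design_bm2(st)
  expect_equal(sort(unique(unname(d2$expected_abundance))),
               sort(unname(ABUNDANCE_TIERS)))
  # low-GC cluster carries the high tier in Bm2
  low_ids <- st$strain_id[st$gc_cluster == "low"]
  expect_true(all(d2$expected_abundance[low_ids] == 8.41))
  d3 <- design_bm3(st)
  high_ids <- st$strain_id[st$gc_cluster == "high"]
  expect_true(all(d3$expected_abundance[high_ids] == 8.41))
  expect_error(build_design(st, "tiered",
                            tier_map = c(low = 1, medium = 2, high = 3)),
               "bijection")
  path <- tempfile(fileext = ".tsv")
  write_design_tsv(d2, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$expected_percent,
               unname(d2$expected_abundance[back$strain_id]))
})
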