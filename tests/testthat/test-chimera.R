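refs2 <- local({
  set.seed(41)
  stats::setNames(c(rand_dna(253), rand_dna(253), rand_dna(253)),
                  c("RA", "RB", "RC"))
})

chimera_of <- function(a, b, bp) {
  paste0(substr(a, 1, bp), substring(b, bp + 1))
}

test_that("best_two_parent_model finds the planted breakpoint", {
  q <- chimera_of(refs2[["RA"]], refs2[["RB"]], 120L)
  m <- best_two_parent_model(q, refs2[["RA"]], refs2[["RB"]])
  expect_equal(m$model_identity, 100)
  # any breakpoint between the last A-only match and the first B-only
  # mismatch is equivalent; the smallest maximiser is reported
  expect_lte(m$breakpoint, 120L)
  pa <- mockamp:::match_profile(q, refs2[["RA"]])
  pb <- mockamp:::match_profile(q, refs2[["RB"]])
  o <- oracle_two_parent(q, pa, pb)
  expect_equal(m$breakpoint, o$breakpoint)
  expect_equal(m$model_identity, o$model_identity)
})

test_that("classify_chimera flags planted chimeras with the right parents", {
  q <- c(chimera_of(refs2[["RA"]], refs2[["RC"]], 100L),
         refs2[["RB"]])
  res <- classify_chimera(q, refs2, mode = "balanced")
  expect_true(res$is_chimera[1])
  expect_equal(res$parent_a[1], "RA")
  expect_equal(res$parent_b[1], "RC")
  expect_false(res$is_chimera[2])
  expect_equal(res$best_single_identity[2], 100)
})

test_that("sensitive mode detects a superset of balanced mode", {
  set.seed(42)
  qs <- c(
    vapply(1:12, function(i) {
      bp <- sample(5:248, 1)
      pr <- sample(names(refs2), 2)
      mutate_seq(chimera_of(refs2[[pr[1]]], refs2[[pr[2]]], bp), 2L)
    }, character(1)),
    vapply(1:6, function(i) mutate_seq(refs2[[sample(3, 1)]], 3L),
           character(1))
  )
  bal <- classify_chimera(qs, refs2, mode = "balanced")$is_chimera
  sen <- classify_chimera(qs, refs2, mode = "sensitive")$is_chimera
  expect_true(all(sen[bal]))
})

test_that("candidate search always includes the best single reference", {
  set.seed(43)
  q <- mutate_seq(refs2[["RB"]], 4L)
  cand <- find_parent_candidates(q, refs2, top_n = 1L)
  expect_true("RB" %in% cand)
})

test_that("detected chimeras on a degraded database are a subset", {
  panel <- make_panel()
  refs <- panel_refs(panel)
  set.seed(44)
  qs <- vapply(1:15, function(i) {
    pr <- sample(names(refs), 2)
    chimera_of(refs[[pr[1]]], refs[[pr[2]]], sample(40:210, 1))
  }, character(1))
  full <- classify_chimera(qs, refs, mode = "balanced")$is_chimera
  degraded <- refs[-seq_len(10)]
  part <- classify_chimera(qs, degraded, mode = "balanced")$is_chimera
  expect_true(all(full[part])) # part subset of full
  acc_full <- chimera_accounting(qs, refs, refs)
  acc_deg <- chimera_accounting(qs, refs, degraded)
  expect_gte(acc_deg$rate_undetected, acc_full$rate_undetected)
})

test_that("chimera_accounting balances true, detected and undetected", {
  panel <- make_panel()
  refs <- panel_refs(panel)
  set.seed(45)
  strains <- vapply(sample(names(refs), 20, replace = TRUE),
                    function(r) refs[[r]], character(1))
  chims <- vapply(1:5, function(i) {
    pr <- sample(names(refs), 2)
    chimera_of(refs[[pr[1]]], refs[[pr[2]]], sample(60:190, 1))
  }, character(1))
  db <- synth_external_db(panel, n_exact = 7L, n_missing = 10L)
  acc <- chimera_accounting(c(strains, chims), refs, db)
  expect_equal(acc$n_reads, 25L)
  expect_equal(acc$n_true, 5L)
  expect_equal(acc$n_undetected, sum(acc$true_chimera &
                                       !acc$detected_chimera))
  expect_equal(acc$rate_true, 100 * acc$n_true / acc$n_reads)
})
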