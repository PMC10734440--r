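refs3 <- local({
  set.seed(51)
  stats::setNames(c(rand_dna(220), rand_dna(220)), c("R1", "R2"))
})

test_that("best_hit picks the closest reference, ties by id", {
  set.seed(52)
  q1 <- mutate_seq(refs3[["R1"]], 3L)
  q2 <- mutate_seq(refs3[["R2"]], 5L)
  h <- best_hit(c(q1, q2, "ACGT"), refs3)
  expect_equal(h$ref_id[1:2], c("R1", "R2"))
  expect_true(h$unalignable[3])
  expect_true(is.na(h$ref_id[3]))
  expect_equal(h$identity[1], 100 * (220 - 3) / 220)
  # exact ties go to the lexicographically smaller reference id
  tie_refs <- c(B = refs3[["R1"]], A = refs3[["R1"]])
  ht <- best_hit(refs3[["R1"]], tie_refs)
  expect_equal(ht$ref_id, "A")
})

test_that("k-mer prescreen in best_hit matches the exhaustive result", {
  panel <- make_panel()
  refs <- panel_refs(panel)
  set.seed(53)
  qs <- vapply(sample(names(refs), 20, replace = TRUE), function(r) {
    mutate_seq(refs[[r]], sample(0:6, 1))
  }, character(1))
  pre <- best_hit(qs, refs) # prescreen active (33 refs > 6)
  full <- best_hit(qs, refs, prescreen_top = length(refs)) # exhaustive
  expect_equal(pre$ref_id, full$ref_id)
  expect_equal(pre$identity, full$identity)
})

test_that("accumulate_errors counts substitutions at the right positions", {
  q <- mutate_at(refs3[["R1"]], c(50, 120))
  ep <- accumulate_errors(q, refs3)
  expect_equal(unname(ep$totals[["subs"]]), 2)
  expect_equal(unname(ep$totals[["valid"]]), 220)
  expect_equal(ep$rate_sub, 100 * 2 / 220)
  expect_setequal(ep$per_position$pos[ep$per_position$n_sub > 0],
                  c(50, 120))
  expect_equal(unname(ep$per_read[1, "n_sub"]), 2L)
})

test_that("accumulate_errors attributes indels to reference positions", {
  ref <- refs3[["R1"]]
  # delete read bases 101-102 (a reference deletion of length 2)
  q_del <- paste0(substr(ref, 1, 100), substring(ref, 103))
  ep <- accumulate_errors(q_del, refs3)
  expect_equal(unname(ep$totals[["dels"]]), 2)
  expect_equal(unname(ep$totals[["subs"]]), 0)
  expect_equal(ep$rate_all, 100 * 2 / (220 - 2))
  # insert two bases after reference position 100
  q_ins <- paste0(substr(ref, 1, 100), "CA", substring(ref, 101))
  ep2 <- accumulate_errors(q_ins, refs3)
  expect_equal(unname(ep2$totals[["ins"]]), 2)
  # attributed to the reference position preceding the insertion (the
  # aligner may shift an ambiguous gap by one position)
  ins_pos <- ep2$per_position$pos[ep2$per_position$n_ins > 0]
  expect_true(all(ins_pos %in% 99:101))
})

test_that("error_grid after-removal strata drop the flagged reads", {
  set.seed(54)
  panel <- make_panel()
  refs <- panel_refs(panel)
  mol <- vapply(sample(names(refs), 8, replace = TRUE),
                function(r) refs[[r]], character(1))
  fwd <- read_set(paste0("r", 1:8), substr(mol, 1, 250),
                  replicate(8, rep(38L, 250), simplify = FALSE))
  rev <- read_set(paste0("r", 1:8),
                  revcomp(substring(mol, 4)),
                  replicate(8, rep(35L, 250), simplify = FALSE))
  eg <- error_grid(fwd, rev, refs, trim_grid = "raw",
                   chimera_ids = c("r1", "r2"))
  before <- eg[eg$read_type == "fwd" & eg$chimera_removal == "before", ]
  after <- eg[eg$read_type == "fwd" & eg$chimera_removal == "after", ]
  expect_equal(before$n_reads, 8L)
  expect_equal(after$n_reads, 6L)
  # noise-free reads: zero error rates everywhere
  expect_true(all(eg$rate_all == 0))
})
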