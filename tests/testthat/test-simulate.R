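panel <- make_panel()
bm1 <- design_bm1(panel)

test_that("sim_params validates inputs", {
  expect_error(sim_params(p_amp = 1.2), "probabilities")
  expect_error(sim_params(cycles_step1 = 40), "<= 35")
  expect_error(sim_params(protocol = "one_step", cycles_step2 = 5),
               "second-step")
  expect_error(sim_params(spacer_fwd = 3, spacer_rev = 3), "sum to 7")
  p <- method_params("two_step_phasing", spacer_fwd = 2L)
  expect_equal(p$protocol, "two_step")
  expect_equal(p$spacer_rev, 5L)
  expect_equal(p$cycles_step1 + p$cycles_step2, 30L)
})

test_that("simulate_pcr is deterministic and labels chimeras consistently", {
  p <- sim_params(seed = 21L, incomplete_ext_prob = 0.02,
                  n_init = 500L, pool_cap = 4000L, frag_cap = 2000L)
  pool1 <- simulate_pcr(bm1, p, n_final = 400L)
  pool2 <- simulate_pcr(bm1, p, n_final = 400L)
  expect_identical(pool1, pool2)
  expect_equal(nrow(pool1), 400L)
  chim <- pool1[pool1$origin == "chimera", ]
  expect_gt(nrow(chim), 0L)
  # two distinct parents, breakpoint strictly inside the product
  expect_true(all(chim$parent_a != chim$parent_b))
  expect_true(all(chim$breakpoint >= 1 &
                    chim$breakpoint < nchar(chim$seq)))
  # chimera prefix comes from parent_a up to polymerase substitutions
  refs <- panel_refs(panel)
  i <- which(pool1$origin == "chimera" & pool1$n_pcr_subs == 0)[1L]
  expect_false(is.na(i))
  bp <- pool1$breakpoint[i]
  expect_equal(substr(pool1$seq[i], 1, bp),
               substr(refs[[pool1$parent_a[i]]], 1, bp))
  expect_equal(substring(pool1$seq[i], bp + 1),
               substring(refs[[pool1$parent_b[i]]], bp + 1))
  # non-chimeric products with no substitutions equal their strain amplicon
  j <- which(pool1$origin == "strain" & pool1$n_pcr_subs == 0)[1L]
  expect_equal(pool1$seq[j], unname(refs[[pool1$parent_a[j]]]))
})

test_that("simulate_reads covers both ends and honours spacers", {
  p <- sim_params(seed = 3L, n_init = 300L, pool_cap = 2000L,
                  frag_cap = 1000L, spacer_fwd = 3L, spacer_rev = 4L)
  pool <- simulate_pcr(bm1, p, n_final = 30L)
  rd <- simulate_reads(pool, p, "libX")
  expect_equal(length(rd$fwd), 30L)
  # amplicons are 253 bp, longer than both effective read lengths
  expect_true(all(nchar(rd$fwd$seq) == 250L - 3L))
  expect_true(all(nchar(rd$rev$seq) == 250L - 4L))
  expect_true(all(unlist(rd$fwd$qual) >= 2L & unlist(rd$fwd$qual) <= 41L))
  expect_equal(rd$truth$read_id, rd$fwd$id)
  expect_equal(rd$truth$origin, pool$origin)
  # sequencing stream independent of pool draw: rerun identical
  rd2 <- simulate_reads(pool, p, "libX")
  expect_identical(rd, rd2)
})

test_that("a noise-free configuration reproduces the amplicons exactly", {
  p <- sim_params(seed = 9L, pol_error_rate = 0, incomplete_ext_prob = 0,
                  qual_decay_fwd = c(41, 41), qual_decay_rev = c(41, 41),
                  qual_sd = 0, n_init = 300L, pool_cap = 2000L,
                  frag_cap = 1000L)
  pool <- simulate_pcr(bm1, p, n_final = 50L)
  expect_true(all(pool$origin == "strain"))
  expect_true(all(pool$n_pcr_subs == 0L))
  rd <- simulate_reads(pool, p)
  refs <- panel_refs(panel)
  # Q41 implies a ~8e-5 per-base miscall rate; with 25k bases a handful of
  # miscalls can occur, so compare against the truth ledger instead
  clean <- which(rd$truth$n_seq_substitutions == 0L)
  expect_gt(length(clean), 0L)
  i <- clean[1L]
  mol <- unname(refs[[pool$parent_a[i]]])
  expect_equal(rd$fwd$seq[i], substr(mol, 1, 250))
  expect_equal(rd$rev$seq[i],
               revcomp(substring(mol, nchar(mol) - 249L)))
})

test_that("inject_contaminants relabels replaced molecules", {
  p <- sim_params(seed = 4L, n_init = 200L, pool_cap = 1500L,
                  frag_cap = 800L)
  pool <- simulate_pcr(bm1, p, n_final = 100L)
  cont <- synth_contaminants(n = 3L)
  set.seed(1)
  out <- inject_contaminants(pool, cont, rate = 0.3)
  hit <- out$origin == "contaminant"
  expect_gt(sum(hit), 0L)
  expect_true(all(out$seq[hit] %in% unname(cont)))
  expect_true(all(out$parent_a[hit] %in% names(cont)))
  expect_identical(inject_contaminants(pool, cont, rate = 0), pool)
})

test_that("truth tables round-trip through TSV", {
  p <- sim_params(seed = 5L, n_init = 200L, pool_cap = 1500L,
                  frag_cap = 800L)
  pool <- simulate_pcr(bm1, p, n_final = 20L)
  rd <- simulate_reads(pool, p, "libT")
  path <- tempfile(fileext = ".tsv")
  write_truth_tsv(rd$truth, path)
  back <- read_truth_tsv(path)
  expect_equal(back, rd$truth)
})
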