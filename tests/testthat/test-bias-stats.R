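test_that("t_test_vs_expected matches stats::t.test and handles zero variance", {
  set.seed(71)
  x <- rnorm(6, mean = 3)
  res <- t_test_vs_expected(x, 2.5)
  ref <- t.test(x, mu = 2.5)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_false(res$degenerate)
  same <- rep(4, 5)
  expect_true(t_test_vs_expected(same, 4)$degenerate)
  expect_equal(t_test_vs_expected(same, 4)$p, 1)
  expect_equal(t_test_vs_expected(same, 5)$p, 0)
})

test_that("anova_lsd reproduces the hand-computed F and letters", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(9, 10, 11))
  res <- anova_lsd(groups)
  # hand sums of squares
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_between <- 3 * sum((vapply(groups, mean, 1) - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  F_hand <- (ss_between / 2) / (ss_within / 6)
  expect_equal(res$F, F_hand)
  expect_equal(unname(res$df), c(2L, 6L))
  expect_equal(res$mse, ss_within / 6)
  # c is separated; a and b share a letter
  expect_equal(res$letters[["a"]], res$letters[["b"]])
  expect_false(res$letters[["c"]] == res$letters[["a"]])
})

test_that("protected LSD collapses letters when the ANOVA is not significant", {
  set.seed(72)
  groups <- list(a = rnorm(4), b = rnorm(4), c = rnorm(4))
  res <- anova_lsd(groups, protected = TRUE)
  if (res$p >= 0.05) {
    expect_true(all(res$letters == res$letters[[1]]))
  }
  # degenerate all-equal input
  deg <- anova_lsd(list(a = c(1, 1), b = c(1, 1)))
  expect_true(deg$degenerate)
})

test_that("pearson correlation hits +/- 1 on exact linear relations", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_observed_expected(2 * x + 1, x), 1)
  expect_equal(pearson_observed_expected(-x, x), -1)
  expect_error(pearson_observed_expected(rep(1, 5), x), "constant")
})

test_that("observed_abundances and bias_report summarise a classified table", {
  panel <- make_panel()
  design <- design_bm1(panel)
  ids <- panel$strain_id
  # two libraries, counts concentrated on three strains
  counts <- matrix(0L, 4, 2,
                   dimnames = list(paste0("OTU", 1:4), c("L1", "L2")))
  counts["OTU1", ] <- c(60L, 58L)
  counts["OTU2", ] <- c(30L, 32L)
  counts["OTU3", ] <- c(10L, 10L)
  counts["OTU4", ] <- c(2L, 1L) # a chimera: excluded from recovery
  ot <- structure(list(
    counts = counts,
    classification = c(OTU1 = paste0("true_strain:", ids[1]),
                       OTU2 = paste0("true_strain:", ids[2]),
                       OTU3 = paste0("true_strain:", ids[1]),
                       OTU4 = "chimera")
  ), class = "otu_table")
  ab <- observed_abundances(ot, design)
  # OTU1 + OTU3 both map to strain 1
  expect_equal(ab$observed[ids[1], "L1"], 100 * 70 / 102)
  expect_equal(ab$observed[ids[2], "L2"], 100 * 32 / 101)
  expect_true(all(ab$observed[ids[4], ] == 0))
  expect_false(any(ab$detected[ids[4], ]))
  rep_bias <- bias_report(ab, design)
  expect_equal(nrow(rep_bias$per_cluster), 3L)
  expect_true(all(is.na(rep_bias$pearson))) # even design: r undefined
  expect_equal(rep_bias$per_strain$expected,
               unname(design$expected_abundance))
})
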