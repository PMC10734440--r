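# Observed-vs-expected quantitation statistics: per-strain recovery,
# one-sample t tests, ANOVA with Fisher's LSD letters, Pearson correlation.

#' Observed per-strain abundances from a classified OTU table
#'
#' The observed percent of strain s in library l is 100 times the summed
#' counts of OTUs classified `true_strain:s` over the library's column
#' total. Strains without any OTU get 0 and are recorded as not detected.
#'
#' @param otu_table An `otu_table` with classification filled.
#' @param design A `mock_design` (defines the strain universe and expected
#'   abundances).
#' @return A list with `observed` (strain x library percent matrix),
#'   `expected` (named percent vector) and `detected` (strain x library
#'   logical matrix).
#' @export
observed_abundances <- function(otu_table, design) {
  stopifnot(!is.null(otu_table$classification))
  strains <- design$strains$strain_id
  counts <- otu_table$counts
  cls <- otu_table$classification[rownames(counts)]
  obs <- matrix(0, nrow = length(strains), ncol = ncol(counts),
                dimnames = list(strains, colnames(counts)))
  for (s in strains) {
    rows <- which(cls == paste0("true_strain:", s))
    if (length(rows) > 0L) {
      obs[s, ] <- colSums(counts[rows, , drop = FALSE])
    }
  }
  tot <- colSums(counts)
  pct <- sweep(obs, 2, ifelse(tot == 0, NA, tot), "/") * 100
  list(observed = pct, expected = design$expected_abundance[strains],
       detected = obs > 0)
}

#' One-sample t test against an expected value
#'
#' @param values Observed values (one per replicate), n >= 2.
#' @param expected The expected value under the design.
#' @return List with `t`, `p` (two-tailed), `mean`, `df`, and `degenerate`
#'   (TRUE when the values have zero variance).
#' @export
t_test_vs_expected <- function(values, expected) {
  values <- values[!is.na(values)]
  n <- length(values)
  stopifnot(n >= 2L)
  if (stats::sd(values) == 0) {
    return(list(t = NA_real_, p = if (mean(values) == expected) 1 else 0,
                mean = mean(values), df = n - 1L, degenerate = TRUE))
  }
  tt <- stats::t.test(values, mu = expected)
  list(t = unname(tt$statistic), p = tt$p.value, mean = mean(values),
       df = n - 1L, degenerate = FALSE)
}

# compact letter display: greedy assignment by descending group mean,
# reusing a letter for every group non-significant against all current
# members of that letter's set
.cld_letters <- function(group_names, means, nonsig) {
  ord <- order(-means)
  sets <- list() # each: character vector of member groups
  for (g in group_names[ord]) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (all(nonsig[g, sets[[k]]])) {
        sets[[k]] <- c(sets[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      sets[[length(sets) + 1L]] <- g
    }
  }
  letters_out <- stats::setNames(rep("", length(group_names)), group_names)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) {
      letters_out[g] <- paste0(letters_out[g], letters[k])
    }
  }
  letters_out
}

#' One-way ANOVA with Fisher's LSD letters
#'
#' Fits a one-way ANOVA and performs pairwise Fisher's LSD tests using the
#' pooled mean squared error; groups are summarised by a compact letter
#' display (groups sharing a letter are pairwise non-significant at
#' `alpha`). By default the LSD tests are protected: when the ANOVA is not
#' significant all groups share one letter.
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param alpha Significance level.
#' @param protected Run the LSD comparisons only when the ANOVA p-value is
#'   below `alpha`.
#' @return List with `F`, `p`, `df`, `mse`, `means`, `letters`, and the
#'   pairwise p-value matrix `p_pairwise`.
#' @export
anova_lsd <- function(groups, alpha = 0.05, protected = TRUE) {
  stopifnot(length(groups) >= 2L, all(vapply(groups, length, 1L) >= 2L))
  gnames <- names(groups)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(gnames, vapply(groups, length, 1L)), levels = gnames)
  if (stats::var(values) == 0) {
    return(list(F = NA_real_, p = NA_real_, degenerate = TRUE,
                means = vapply(groups, mean, 1),
                letters = stats::setNames(rep("a", length(groups)), gnames),
                p_pairwise = NULL))
  }
  fit <- stats::aov(values ~ fac)
  an <- stats::anova(fit)
  Fval <- an[["F value"]][1L]
  pval <- an[["Pr(>F)"]][1L]
  mse <- an[["Mean Sq"]][2L]
  df_err <- an[["Df"]][2L]
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  k <- length(groups)
  p_pair <- matrix(NA_real_, k, k, dimnames = list(gnames, gnames))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      tval <- (means[i] - means[j]) / se
      p_pair[i, j] <- p_pair[j, i] <- 2 * stats::pt(-abs(tval), df_err)
    }
  }
  diag(p_pair) <- 1
  nonsig <- if (protected && pval >= alpha) {
    matrix(TRUE, k, k, dimnames = list(gnames, gnames))
  } else {
    p_pair >= alpha
  }
  list(F = Fval, p = pval, df = c(k - 1L, df_err), mse = mse, means = means,
       letters = .cld_letters(gnames, means, nonsig), p_pairwise = p_pair,
       degenerate = FALSE)
}

#' Pearson correlation between observed and expected abundances
#'
#' @param observed,expected Numeric vectors of equal length (>= 3), both
#'   non-constant.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_observed_expected <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 3L)
  if (stats::sd(observed) == 0 || stats::sd(expected) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(observed, expected)
}

#' Observed-vs-expected bias report for one community
#'
#' Per-strain recovery (mean, sd, fold difference), per-GC-cluster
#' one-sample t tests against the expected tier with LSD letters across
#' clusters, and per-library Pearson correlations.
#'
#' @param abund Result of [observed_abundances()].
#' @param design The `mock_design` used.
#' @param alpha Significance level for the LSD letters.
#' @return A `bias_report` list: `per_strain` data.frame, `per_cluster`
#'   data.frame (cluster, expected, observed mean, p, letter), `pearson`
#'   (per-library r), `summary` (mean and sd of r).
#' @export
bias_report <- function(abund, design, alpha = 0.05) {
  obs <- abund$observed
  exp_pct <- abund$expected
  per_strain <- data.frame(
    strain_id = rownames(obs),
    expected = unname(exp_pct),
    observed_mean = rowMeans(obs, na.rm = TRUE),
    observed_sd = apply(obs, 1, stats::sd, na.rm = TRUE),
    detected_in = rowSums(abund$detected),
    stringsAsFactors = FALSE
  )
  per_strain$fold_difference <- ifelse(per_strain$expected > 0,
                                       per_strain$observed_mean /
                                         per_strain$expected, NA)
  cl <- design$strains$gc_cluster[match(rownames(obs),
                                        design$strains$strain_id)]
  clusters <- c("low", "medium", "high")
  clusters <- clusters[clusters %in% cl]
  # per-library cluster means (one value per replicate library)
  groups <- lapply(clusters, function(cc) {
    colMeans(obs[cl == cc, , drop = FALSE], na.rm = TRUE)
  })
  names(groups) <- clusters
  lsd <- if (length(groups) >= 2L && ncol(obs) >= 2L) {
    anova_lsd(groups, alpha = alpha)
  } else NULL
  per_cluster <- do.call(rbind, lapply(clusters, function(cc) {
    expc <- mean(exp_pct[cl == cc])
    vals <- groups[[cc]]
    tt <- if (length(vals) >= 2L) t_test_vs_expected(vals, expc) else
      list(p = NA_real_)
    data.frame(cluster = cc, expected = expc, observed_mean = mean(vals),
               observed_sd = stats::sd(vals), p_value = tt$p,
               letter = if (!is.null(lsd)) lsd$letters[[cc]] else NA,
               stringsAsFactors = FALSE)
  }))
  # undefined for even designs (constant expected vector): NA
  r <- apply(obs, 2, function(o) {
    if (stats::sd(o, na.rm = TRUE) == 0 || stats::sd(exp_pct) == 0) {
      NA_real_
    } else {
      pearson_observed_expected(o, unname(exp_pct))
    }
  })
  structure(list(per_strain = per_strain, per_cluster = per_cluster,
                 pearson = r,
                 summary = c(mean_r = mean(r, na.rm = TRUE),
                             sd_r = stats::sd(r, na.rm = TRUE)),
                 anova = lsd),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Bias report\n")
  print(x$per_cluster, row.names = FALSE)
  cat(sprintf("Pearson r: %.3f +/- %.3f over %d libraries\n",
              x$summary[["mean_r"]], x$summary[["sd_r"]], length(x$pearson)))
  invisible(x)
}
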