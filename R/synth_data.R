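# Synthetic stand-ins for the wet-lab inputs: a 33-strain reference set with
# the documented GC-cluster structure, a contaminant pool, and an external
# 16S database emulating an incomplete public reference set.

# Design values of the mock community: three 11-strain clusters whose V4
# GC contents average 51.16 / 55.1 / 59.3 percent (spreads 2.1 / 1.8 / 3.3).
.GC_CLUSTER_MEAN <- c(low = 51.16, medium = 55.1, high = 59.3)
.GC_CLUSTER_SD <- c(low = 2.1, medium = 1.8, high = 3.3)

# Derive a strain V4 insert from the common ancestor: first substitute just
# enough A/T <-> G/C positions to hit the strain's target GC count exactly,
# then add GC-preserving substitutions (A<->T, C<->G) up to n_div changes.
.derive_from_ancestor <- function(ancestor, gc_target_percent, n_div) {
  ch <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
  len <- length(ch)
  is_gc <- ch %in% c("G", "C")
  target <- round(len * gc_target_percent / 100)
  delta <- target - sum(is_gc)
  changed <- integer(0)
  if (delta > 0L) {
    changed <- sample(which(!is_gc), delta)
    ch[changed] <- sample(c("G", "C"), delta, replace = TRUE)
  } else if (delta < 0L) {
    changed <- sample(which(is_gc), -delta)
    ch[changed] <- sample(c("A", "T"), -delta, replace = TRUE)
  }
  n_rest <- max(0L, n_div - length(changed))
  if (n_rest > 0L) {
    swap <- c(A = "T", T = "A", C = "G", G = "C")
    pos <- sample(setdiff(seq_len(len), changed), n_rest)
    ch[pos] <- unname(swap[ch[pos]])
  }
  paste(ch, collapse = "")
}

# Concrete realisation of a degenerate primer: each IUPAC code replaced by a
# random member of its base set.
.concretize_primer <- function(primer) {
  ch <- strsplit(primer, "", fixed = TRUE)[[1L]]
  paste(vapply(ch, function(b) {
    opts <- .IUPAC[[b]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic 33-strain mock reference set
#'
#' Builds near full-length synthetic 16S stand-ins whose V4 inserts realise
#' the mock community's documented GC-cluster design: three clusters of
#' `n_per_cluster` strains with cluster mean GC contents of 51.16, 55.1 and
#' 59.3 percent. Within each cluster the target GC values are spread evenly
#' across mean +/- one cluster spread, so the cluster means are met exactly
#' up to base-count granularity and the clusters do not overlap in rank.
#'
#' All V4 inserts are derived from one common ancestral insert by point
#' substitutions (see `ancestor_divergence`), so the strains form a
#' homologous family, as real 16S V4 sequences do: pairwise identities land
#' around 75-80 percent rather than the ~45 percent of unrelated random
#' sequences. Reference-guided chimera detection relies on this homology --
#' with unrelated references the ends-free alignment of a chimera against
#' its minor parent degenerates whenever the minor segment is short, and
#' near-breakpoint-end chimeras become undetectable in principle.
#'
#' Each full sequence is pad + forward-primer site + V4 insert +
#' reverse-primer site + pad; a configurable number of strains carry
#' mismatches in their forward primer site, emulating the low-recovery
#' strains whose amplification is suppressed.
#'
#' @param n_per_cluster Strains per GC cluster (11 in the study design).
#' @param v4_length Insert length in bases (253 for the V4 region).
#' @param n_primer_mismatch_strains How many strains receive forward-primer
#'   mismatches (the first gets 1 mismatch, the second 2, further ones cycle).
#' @param pad Length of the flanking sequence outside the primer sites.
#' @param ancestor_divergence Fraction of insert positions substituted per
#'   strain relative to the common ancestor (0.12 gives ~22 percent pairwise
#'   divergence, typical of V4 regions across phyla).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A [strain_table()] with attribute `cluster_truth`, a named
#'   character vector of the intended cluster memberships (the analogue of a
#'   published membership table usable as `overrides` in
#'   [assign_gc_clusters()]).
#' @export
synth_mock_strains <- function(n_per_cluster = 11L, v4_length = 253L,
                               n_primer_mismatch_strains = 2L, pad = 40L,
                               ancestor_divergence = 0.12, seed = 20231L) {
  set.seed(seed)
  clusters <- c("low", "medium", "high")
  spread <- if (n_per_cluster > 1L) {
    seq(-1, 1, length.out = n_per_cluster)
  } else 0
  gc_targets <- unlist(lapply(clusters, function(cl) {
    .GC_CLUSTER_MEAN[[cl]] + .GC_CLUSTER_SD[[cl]] * spread
  }))
  n <- 3L * n_per_cluster
  ids <- sprintf("SYN%02d", seq_len(n))
  cluster_truth <- stats::setNames(rep(clusters, each = n_per_cluster), ids)
  mm_strains <- if (n_primer_mismatch_strains > 0L) {
    # spread the suppressed strains across clusters
    ids[round(seq(1L, n, length.out = n_primer_mismatch_strains + 2L))[
      seq_len(n_primer_mismatch_strains) + 1L]]
  } else character(0)
  ancestor <- seq_with_gc(v4_length, mean(.GC_CLUSTER_MEAN))
  n_div <- round(ancestor_divergence * v4_length)
  full <- character(n)
  for (i in seq_len(n)) {
    fwd_site <- .concretize_primer(PRIMER_515F)
    if (ids[i] %in% mm_strains) {
      n_mm <- (match(ids[i], mm_strains) - 1L) %% 2L + 1L
      ch <- strsplit(fwd_site, "", fixed = TRUE)[[1L]]
      pos <- c(5L, 12L)[seq_len(n_mm)]
      for (p in pos) ch[p] <- sample(setdiff(.DNA_BASES, .IUPAC[[substr(
        PRIMER_515F, p, p)]]), 1L)
      fwd_site <- paste(ch, collapse = "")
    }
    rev_site <- revcomp(.concretize_primer(PRIMER_806R))
    insert <- .derive_from_ancestor(ancestor, gc_targets[i], n_div)
    full[i] <- paste0(random_dna(1, pad), fwd_site, insert, rev_site,
                      random_dna(1, pad))
  }
  st <- strain_table(ids, full, phylum = sprintf("SynPhylum%02d", seq_len(n)))
  attr(st, "cluster_truth") <- cluster_truth
  st
}

#' Synthetic contaminant amplicons
#'
#' Random sequences far below 70% identity to any synthetic strain, standing
#' in for reagent/laboratory contaminants.
#'
#' @param n Number of contaminants.
#' @param len Sequence length.
#' @param seed Integer seed.
#' @return Named character vector (`CONT01`, ...).
#' @export
synth_contaminants <- function(n = 20L, len = 253L, seed = 4242L) {
  set.seed(seed)
  stats::setNames(random_dna(n, len, gc = stats::runif(1, 0.4, 0.6)),
                  sprintf("CONT%02d", seq_len(n)))
}

#' Synthetic external reference database
#'
#' Emulates an incomplete public 16S database: most strains are represented
#' by a slightly diverged relative, a few by identical sequences, and some
#' strains are absent altogether. Chimeras whose parents are absent or too
#' diverged escape detection against this set, which is the mechanism behind
#' undetected chimeras.
#'
#' @param strains Strain table with `v4_seq` filled.
#' @param divergence Per-base substitution fraction of the diverged entries.
#' @param n_exact Number of strains represented identically.
#' @param n_missing Number of strains absent from the database.
#' @param contaminants Optional named vector of contaminant sequences to
#'   include (so contaminants can be recognised as database hits).
#' @param seed Integer seed.
#' @return Named character vector of database sequences.
#' @export
synth_external_db <- function(strains, divergence = 0.015, n_exact = 7L,
                              n_missing = 5L, contaminants = NULL,
                              seed = 777L) {
  set.seed(seed)
  ok <- !is.na(strains$v4_seq)
  ids <- strains$strain_id[ok]
  seqs <- strains$v4_seq[ok]
  n <- length(ids)
  stopifnot(n_exact + n_missing <= n)
  perm <- sample.int(n)
  exact_idx <- perm[seq_len(n_exact)]
  missing_idx <- perm[n_exact + seq_len(n_missing)]
  keep <- setdiff(seq_len(n), missing_idx)
  db <- vapply(keep, function(i) {
    if (i %in% exact_idx) return(seqs[i])
    mutate_seq(seqs[i], round(nchar(seqs[i]) * divergence))
  }, character(1))
  names(db) <- paste0("DB_", ids[keep])
  c(db, if (!is.null(contaminants)) {
    stats::setNames(unname(contaminants), paste0("DB_", names(contaminants)))
  })
}
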