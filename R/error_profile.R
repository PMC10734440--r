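# Best-hit alignment of reads to references and error-rate estimation.

#' Best-hit reference for each read
#'
#' Aligns every read against every reference (ends-free global alignment)
#' and returns the reference maximizing identity (matches over read length),
#' ties broken by lexicographically smaller reference id. Reads shorter than
#' 50 bases are flagged unalignable.
#'
#' @param seqs Character vector of read sequences.
#' @param refs Named character vector of reference sequences.
#' @param min_len Reads shorter than this are flagged unalignable.
#' @param k k-mer length for the prescreen.
#' @param prescreen_top With more than `prescreen_top` references, each read
#'   is aligned only against the `prescreen_top` references sharing the most
#'   k-mers with it (all references when no k-mer is shared); with
#'   `prescreen_top` references or fewer, all alignments are computed.
#' @return A data.frame with `ref_id`, `identity` and `unalignable`.
#' @export
best_hit <- function(seqs, refs, min_len = 50L, k = 8L, prescreen_top = 6L) {
  stopifnot(length(refs) > 0L)
  refs <- refs[order(names(refs))]
  n <- length(seqs)
  nref <- length(refs)
  out <- data.frame(ref_id = NA_character_, identity = NA_real_,
                    unalignable = nchar(seqs) < min_len,
                    stringsAsFactors = FALSE)[rep(1L, max(n, 1L)), ]
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out$unalignable <- nchar(seqs) < min_len
  ok <- which(!out$unalignable)
  if (length(ok) > 0L) {
    qs <- seqs[ok]
    idmat <- matrix(-Inf, nrow = length(ok), ncol = nref,
                    dimnames = list(NULL, names(refs)))
    if (nref <= prescreen_top) {
      for (j in seq_len(nref)) {
        idmat[, j] <- identity_to_ref(qs, refs[[j]])
      }
    } else {
      share <- .kmer_share_matrix(qs, refs, k)
      pres_list <- lapply(seq_along(ok), function(i) {
        sh <- share[i, ]
        if (all(sh == 0)) return(names(refs))
        names(refs)[order(-sh, names(refs))][seq_len(prescreen_top)]
      })
      need <- split(rep(seq_along(ok), lengths(pres_list)),
                    unlist(pres_list))
      for (rid in names(need)) {
        qi <- need[[rid]]
        idmat[qi, rid] <- identity_to_ref(qs[qi], refs[[rid]])
      }
    }
    best <- max.col(idmat, ties.method = "first")
    out$ref_id[ok] <- names(refs)[best]
    out$identity[ok] <- idmat[cbind(seq_along(ok), best)]
  }
  out
}

#' Accumulate per-position alignment errors against best-hit references
#'
#' Aligns each read to its best-hit reference and tallies substitutions,
#' insertions (read bases opposite a reference gap, attributed to the
#' preceding reference position) and deletions (reference bases opposite a
#' read gap) at each reference position. Valid bases are read bases aligned
#' to a reference base.
#'
#' @param seqs Character vector of read sequences.
#' @param refs Named character vector of references.
#' @param hits Optional precomputed [best_hit()] table.
#' @param stratum Optional named list of stratum labels carried through.
#' @return An `error_profile` object: list with `per_position` (data.frame
#'   `ref_id`, `pos`, `n_sub`, `n_ins`, `n_del`, `n_valid`), `per_read`
#'   (read x {n_sub, n_ins, n_del, n_valid} count matrix, zero rows for
#'   unalignable reads), `totals` (named vector subs/ins/dels/valid),
#'   `rate_sub` and `rate_all` in percent, `n_reads`, `n_unalignable`,
#'   `stratum`.
#' @export
accumulate_errors <- function(seqs, refs, hits = NULL, stratum = list()) {
  refs <- refs[order(names(refs))]
  if (is.null(hits)) hits <- best_hit(seqs, refs)
  per_ref <- list()
  per_read <- matrix(0L, nrow = length(seqs), ncol = 4,
                     dimnames = list(NULL, c("n_sub", "n_ins", "n_del",
                                             "n_valid")))
  tot <- c(subs = 0, ins = 0, dels = 0, valid = 0)
  for (rid in unique(stats::na.omit(hits$ref_id))) {
    idx <- which(!hits$unalignable & hits$ref_id == rid)
    if (length(idx) == 0L) next
    ref <- refs[[rid]]
    L <- nchar(ref)
    counts <- matrix(0L, nrow = L, ncol = 4,
                     dimnames = list(NULL, c("n_sub", "n_ins", "n_del",
                                             "n_valid")))
    aln <- align_to_ref(seqs[idx], ref)
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    s_start <- Biostrings::start(Biostrings::subject(aln))
    for (i in seq_along(idx)) {
      p <- strsplit(pat[i], "", fixed = TRUE)[[1L]]
      s <- strsplit(sub[i], "", fixed = TRUE)[[1L]]
      sb <- s != "-"
      pb <- p != "-"
      rpos <- s_start[i] - 1L + cumsum(sb)
      both <- pb & sb
      subst <- both & p != s
      insr <- pb & !sb
      delr <- !pb & sb
      if (any(both)) {
        t <- tabulate(rpos[both], nbins = L)
        counts[, "n_valid"] <- counts[, "n_valid"] + t
      }
      if (any(subst)) {
        t <- tabulate(rpos[subst], nbins = L)
        counts[, "n_sub"] <- counts[, "n_sub"] + t
      }
      if (any(insr)) {
        t <- tabulate(pmax(rpos[insr], 1L), nbins = L)
        counts[, "n_ins"] <- counts[, "n_ins"] + t
      }
      if (any(delr)) {
        t <- tabulate(rpos[delr], nbins = L)
        counts[, "n_del"] <- counts[, "n_del"] + t
      }
      per_read[idx[i], ] <- c(sum(subst), sum(insr), sum(delr), sum(both))
    }
    tot <- tot + c(subs = sum(counts[, "n_sub"]),
                   ins = sum(counts[, "n_ins"]),
                   dels = sum(counts[, "n_del"]),
                   valid = sum(counts[, "n_valid"]))
    keep <- rowSums(counts) > 0
    if (any(keep)) {
      per_ref[[rid]] <- data.frame(ref_id = rid, pos = which(keep),
                                   counts[keep, , drop = FALSE])
    }
  }
  per_position <- if (length(per_ref) > 0L) {
    do.call(rbind, c(per_ref, list(make.row.names = FALSE)))
  } else {
    data.frame(ref_id = character(0), pos = integer(0), n_sub = integer(0),
               n_ins = integer(0), n_del = integer(0), n_valid = integer(0))
  }
  res <- list(
    per_position = per_position, per_read = per_read, totals = tot,
    rate_sub = if (tot[["valid"]] > 0) 100 * tot[["subs"]] / tot[["valid"]]
               else NA_real_,
    rate_all = if (tot[["valid"]] > 0) {
      100 * (tot[["subs"]] + tot[["ins"]] + tot[["dels"]]) / tot[["valid"]]
    } else NA_real_,
    n_reads = length(seqs), n_unalignable = sum(hits$unalignable),
    stratum = stratum
  )
  class(res) <- "error_profile"
  res
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    "Error profile: %d reads, %d valid bases; substitution rate %.4f%%, all-error rate %.4f%%\n",
    x$n_reads, x$totals[["valid"]], x$rate_sub, x$rate_all))
  invisible(x)
}

#' Error rates across the trimming grid, before and after chimera removal
#'
#' For each trimming level: trims and filters both mates, merges pairs, and
#' estimates the error rate of the forward, reverse and merged reads, both
#' for all reads and excluding reads flagged chimeric.
#'
#' @param fwd,rev Forward and reverse [read_set()]s of one library.
#' @param refs Named character vector of references.
#' @param trim_grid Subset of [TRIM_GRID].
#' @param chimera_ids Character vector of read ids flagged chimeric; the
#'   "after removal" strata exclude them.
#' @param min_len Minimum post-trim read length.
#' @param max_reads Optional per-stratum cap on the number of reads aligned
#'   (the leading reads are used; read order is already random for
#'   simulated data).
#' @return A data.frame with one row per (trim level x read type x
#'   before/after removal): stratum labels, read and base counts, and
#'   `rate_sub` / `rate_all` in percent.
#' @export
error_grid <- function(fwd, rev, refs, trim_grid = TRIM_GRID,
                       chimera_ids = character(0), min_len = 200L,
                       max_reads = Inf) {
  stopifnot(all(trim_grid %in% TRIM_GRID))
  rows <- list()
  for (level in trim_grid) {
    qc <- qc_library(fwd, rev, level, min_len = min_len)
    sets <- list(fwd = qc$fwd, rev = qc$rev, merged = qc$merged)
    for (type in names(sets)) {
      rs <- sets[[type]]
      if (length(rs) > max_reads) rs <- rs[seq_len(max_reads)]
      seqs <- rs$seq
      # reverse reads are sequenced from the opposite strand
      if (type == "rev") seqs <- revcomp(seqs)
      # align once per stratum; before/after strata are per-read subsets
      ep <- accumulate_errors(seqs, refs)
      for (removal in c("before", "after")) {
        use <- if (removal == "after") !(rs$id %in% chimera_ids)
               else rep(TRUE, length(rs))
        prt <- colSums(ep$per_read[use, , drop = FALSE])
        valid <- prt[["n_valid"]]
        rows[[length(rows) + 1L]] <- data.frame(
          trim_level = level, read_type = type, chimera_removal = removal,
          n_reads = sum(use), valid_bases = valid,
          n_sub = prt[["n_sub"]], n_ins = prt[["n_ins"]],
          n_del = prt[["n_del"]],
          rate_sub = if (valid > 0) 100 * prt[["n_sub"]] / valid else
            NA_real_,
          rate_all = if (valid > 0) {
            100 * (prt[["n_sub"]] + prt[["n_ins"]] + prt[["n_del"]]) / valid
          } else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
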