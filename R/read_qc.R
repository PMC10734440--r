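# Quality trimming, length/ambiguity filtering, and overlap merging.

#' The quality-trimming stringency grid
#'
#' Labels of the trimming levels evaluated throughout: raw (no trimming) and
#' all combinations of quality thresholds 20/25/30 with window sizes 5 and 2.
#' @export
TRIM_GRID <- c("raw", "Q20-W5", "Q25-W5", "Q30-W5",
               "Q20-W2", "Q25-W2", "Q30-W2")

# parse "Q25-W5" -> list(q = 25, w = 5); "raw" -> NULL
parse_trim_level <- function(level) {
  if (identical(level, "raw")) return(NULL)
  m <- regmatches(level, regexec("^Q([0-9]+)-W([0-9]+)$", level))[[1L]]
  if (length(m) != 3L) stop("unparseable trim level: ", level)
  list(q = as.integer(m[2L]), w = as.integer(m[3L]))
}

#' Sliding-window quality trimming
#'
#' Keeps the longest contiguous segment of the read such that every
#' length-`window` window fully inside it has mean quality at least
#' `q_threshold` (leftmost on ties). Segments shorter than the window are
#' admitted only when their own mean passes, and only when no window-length
#' segment passes. With `mode = "first_fail"` the read is instead cut at
#' the first failing window, keeping only the passing prefix.
#'
#' @param seq Nucleotide string.
#' @param qual Integer Phred qualities, one per base.
#' @param q_threshold Window mean-quality threshold.
#' @param window Window size in bases.
#' @param mode `"longest"` (default) or `"first_fail"`.
#' @return List with `seq`, `qual`, and the kept 1-based `start`/`end`
#'   (0 and -1 when everything is trimmed).
#' @export
trim_sliding <- function(seq, qual, q_threshold, window, mode = c("longest",
                                                                  "first_fail")) {
  mode <- match.arg(mode)
  stopifnot(window >= 1L, nchar(seq) == length(qual))
  n <- length(qual)
  empty <- list(seq = "", qual = integer(0), start = 0L, end = -1L)
  if (n == 0L) return(empty)
  if (n >= window) {
    cs <- c(0, cumsum(qual))
    nwin <- n - window + 1L
    wmean <- (cs[(window + 1L):(n + 1L)] - cs[1:nwin]) / window
    pass <- wmean >= q_threshold
    if (any(pass)) {
      r <- rle(pass)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      if (mode == "first_fail") {
        if (!pass[1L]) return(empty)
        j1 <- starts[runs[1L]]
        j2 <- ends[runs[1L]]
      } else {
        lens <- r$lengths[runs]
        best <- runs[which.max(lens)] # which.max takes the first maximum
        j1 <- starts[best]
        j2 <- ends[best]
      }
      s <- j1
      e <- j2 + window - 1L
      return(list(seq = substr(seq, s, e), qual = qual[s:e],
                  start = s, end = e))
    }
    if (mode == "first_fail") return(empty)
  }
  # no window-length segment passes: best short segment (length < window)
  maxlen <- min(n, window - 1L)
  for (len in rev(seq_len(maxlen))) {
    if (len == 0L) break
    for (s in seq_len(n - len + 1L)) {
      if (mean(qual[s:(s + len - 1L)]) >= q_threshold) {
        e <- s + len - 1L
        return(list(seq = substr(seq, s, e), qual = qual[s:e],
                    start = s, end = e))
      }
    }
  }
  empty
}

#' Trim every read of a set
#'
#' @param reads A [read_set()].
#' @param level A [TRIM_GRID] label (`"raw"` is a no-op).
#' @inheritParams trim_sliding
#' @return A trimmed [read_set()]; fully trimmed reads become empty reads.
#' @export
trim_reads <- function(reads, level, mode = "longest") {
  spec <- parse_trim_level(level)
  if (is.null(spec)) return(reads)
  n <- length(reads)
  seqs <- character(n)
  quals <- vector("list", n)
  for (i in seq_len(n)) {
    t <- trim_sliding(reads$seq[i], reads$qual[[i]], spec$q, spec$w,
                      mode = mode)
    seqs[i] <- t$seq
    quals[[i]] <- t$qual
  }
  read_set(reads$id, seqs, quals)
}

#' Length and ambiguity filter
#'
#' Drops reads shorter than `min_len` bases or containing `N`.
#'
#' @param seq Nucleotide string.
#' @param min_len Minimum length in bases.
#' @return List with `keep` (logical) and `reason` (`NA`, `"short"` or
#'   `"ambiguous"`).
#' @export
filter_read <- function(seq, min_len = 200L) {
  if (nchar(seq) < min_len) {
    list(keep = FALSE, reason = "short")
  } else if (grepl("N", seq, fixed = TRUE)) {
    list(keep = FALSE, reason = "ambiguous")
  } else {
    list(keep = TRUE, reason = NA_character_)
  }
}

#' @rdname filter_read
#' @param reads A [read_set()].
#' @return `filter_reads` returns a list with the kept `reads`, and drop
#'   counts `n_short` and `n_ambiguous`.
#' @export
filter_reads <- function(reads, min_len = 200L) {
  short <- nchar(reads$seq) < min_len
  ambig <- !short & grepl("N", reads$seq, fixed = TRUE)
  list(reads = reads[!(short | ambig)],
       n_short = sum(short), n_ambiguous = sum(ambig))
}

#' Merge a read pair by best overlap
#'
#' The reverse read is reverse-complemented (qualities reversed), then all
#' overlap lengths of at least `min_overlap` are scored; the overlap with
#' the lowest mismatch fraction wins (ties: longest overlap). Within the
#' overlap the higher-quality base is emitted; merged quality is the max of
#' the two on agreement and their absolute difference (floor 2) on conflict.
#'
#' @param fwd_seq,fwd_qual Forward read and qualities.
#' @param rev_seq,rev_qual Reverse read and qualities (as sequenced).
#' @param min_overlap Minimum overlap length in bases.
#' @param max_mismatch_frac Maximum mismatch fraction of the best overlap.
#' @return On success, list with `merged = TRUE`, `seq`, `qual`, `overlap`,
#'   `mismatch_frac`; otherwise `merged = FALSE` with `reason`
#'   (`"no_overlap"` or `"too_divergent"`).
#' @export
merge_pairs <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                        min_overlap = 20L, max_mismatch_frac = 0.25) {
  nf <- nchar(fwd_seq)
  nr <- nchar(rev_seq)
  if (min(nf, nr) < min_overlap) {
    return(list(merged = FALSE, reason = "no_overlap"))
  }
  rc <- revcomp(rev_seq)
  rq <- rev(rev_qual)
  f <- strsplit(fwd_seq, "", fixed = TRUE)[[1L]]
  r <- strsplit(rc, "", fixed = TRUE)[[1L]]
  best_o <- NA_integer_
  best_mf <- Inf
  for (o in min_overlap:min(nf, nr)) {
    mm <- sum(f[(nf - o + 1L):nf] != r[1:o])
    mf <- mm / o
    if (mf < best_mf || (mf == best_mf && !is.na(best_o) && o > best_o)) {
      best_mf <- mf
      best_o <- o
    }
  }
  if (best_mf > max_mismatch_frac) {
    return(list(merged = FALSE, reason = "too_divergent"))
  }
  o <- best_o
  fo <- (nf - o + 1L):nf
  ro <- 1:o
  agree <- f[fo] == r[ro]
  take_f <- agree | fwd_qual[fo] >= rq[ro]
  cons <- ifelse(take_f, f[fo], r[ro])
  consq <- ifelse(agree, pmax(fwd_qual[fo], rq[ro]),
                  pmax(2L, abs(fwd_qual[fo] - rq[ro])))
  seq <- paste0(substr(fwd_seq, 1L, nf - o), paste(cons, collapse = ""),
                substr(rc, o + 1L, nr))
  qual <- c(fwd_qual[seq_len(nf - o)], as.integer(consq), rq[seq_len(nr - o) + o])
  list(merged = TRUE, seq = seq, qual = qual, overlap = o,
       mismatch_frac = best_mf)
}

#' Merge all pairs of two read sets
#'
#' Pairs reads by position (ids must agree), merging each with
#' [merge_pairs()].
#'
#' @param fwd,rev Forward and reverse [read_set()]s.
#' @inheritParams merge_pairs
#' @return List with `merged` (a [read_set()] of joined reads), and counts
#'   `n_no_overlap`, `n_too_divergent`.
#' @export
merge_read_sets <- function(fwd, rev, min_overlap = 20L,
                            max_mismatch_frac = 0.25) {
  stopifnot(identical(fwd$id, rev$id))
  n <- length(fwd)
  ids <- character(0); seqs <- character(0); quals <- list()
  n_no <- 0L; n_div <- 0L
  for (i in seq_len(n)) {
    m <- merge_pairs(fwd$seq[i], fwd$qual[[i]], rev$seq[i], rev$qual[[i]],
                     min_overlap = min_overlap,
                     max_mismatch_frac = max_mismatch_frac)
    if (isTRUE(m$merged)) {
      ids <- c(ids, fwd$id[i])
      seqs <- c(seqs, m$seq)
      quals <- c(quals, list(m$qual))
    } else if (m$reason == "no_overlap") {
      n_no <- n_no + 1L
    } else {
      n_div <- n_div + 1L
    }
  }
  list(merged = read_set(ids, seqs, quals), n_no_overlap = n_no,
       n_too_divergent = n_div)
}

#' Per-library QC: trim, filter, merge
#'
#' Applies one trimming level to both mates, drops short/ambiguous reads,
#' and merges the surviving pairs.
#'
#' @param fwd,rev Forward and reverse [read_set()]s.
#' @param level A [TRIM_GRID] label.
#' @param min_len Minimum post-trim read length.
#' @inheritParams merge_pairs
#' @return List with `fwd`, `rev` (trimmed+filtered, pair-synchronised),
#'   `merged` (a [read_set()]), and a one-row `summary` data.frame.
#' @export
qc_library <- function(fwd, rev, level = "raw", min_len = 200L,
                       min_overlap = 20L, max_mismatch_frac = 0.25) {
  n_in <- length(fwd)
  tf <- trim_reads(fwd, level)
  tr <- trim_reads(rev, level)
  keep_f <- vapply(seq_along(tf$id), function(i) {
    filter_read(tf$seq[i], min_len)$keep
  }, logical(1))
  keep_r <- vapply(seq_along(tr$id), function(i) {
    filter_read(tr$seq[i], min_len)$keep
  }, logical(1))
  keep <- keep_f & keep_r
  tf <- tf[keep]
  tr <- tr[keep]
  mg <- merge_read_sets(tf, tr, min_overlap, max_mismatch_frac)
  summary <- data.frame(
    trim_level = level, reads_in = n_in, pairs_kept = sum(keep),
    pairs_dropped = n_in - sum(keep), merged = length(mg$merged),
    rejected_no_overlap = mg$n_no_overlap,
    rejected_divergent = mg$n_too_divergent
  )
  list(fwd = tf, rev = tr, merged = mg$merged, summary = summary)
}
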