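# Brute-force reference implementations (oracles) used by the module and
# acceptance suites. Deliberately written as direct restatements of the
# definitions, with no shortcuts shared with the package implementations
# (except the low-level pairwise aligner, which both sides consume as a
# primitive).

# --- random inputs ---------------------------------------------------------

rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rand_quals <- function(n, lo = 2L, hi = 41L) {
  sample(lo:hi, n, replace = TRUE)
}

# --- IUPAC window-scan oracle for match_primer -----------------------------

.iupac_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_match_primer <- function(seq, primer, max_mismatch = 2L) {
  s <- strsplit(seq, "")[[1L]]
  p <- strsplit(primer, "")[[1L]]
  L <- length(s)
  k <- length(p)
  pos <- integer(0)
  mm <- integer(0)
  if (L >= k) {
    for (i in 0:(L - k)) {
      n_mm <- 0L
      for (j in seq_len(k)) {
        if (!(s[i + j] %in% .iupac_oracle[[p[j]]])) n_mm <- n_mm + 1L
      }
      if (n_mm <= max_mismatch) {
        pos <- c(pos, i)
        mm <- c(mm, n_mm)
      }
    }
  }
  data.frame(position = pos, mismatches = mm)
}

# --- exhaustive-substring oracle for trim_sliding (mode = "longest") -------

oracle_trim_longest <- function(qual, q_threshold, window) {
  n <- length(qual)
  # candidates of length >= window: every full window inside must pass;
  # longest first, leftmost on ties
  if (n >= window) {
    for (len in n:window) {
      for (s in 1:(n - len + 1L)) {
        e <- s + len - 1L
        ok <- TRUE
        for (ws in s:(e - window + 1L)) {
          if (mean(qual[ws:(ws + window - 1L)]) < q_threshold) {
            ok <- FALSE
            break
          }
        }
        if (ok) return(c(start = s, end = e))
      }
    }
  }
  # fallback: short segments (length < window) by their own mean
  maxlen <- min(n, window - 1L)
  if (maxlen >= 1L) {
    for (len in maxlen:1) {
      for (s in 1:(n - len + 1L)) {
        e <- s + len - 1L
        if (mean(qual[s:e]) >= q_threshold) return(c(start = s, end = e))
      }
    }
  }
  c(start = 0L, end = -1L)
}

# --- all-offsets oracle for merge_pairs ------------------------------------

oracle_merge <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                         min_overlap = 20L, max_mismatch_frac = 0.25) {
  nf <- nchar(fwd_seq)
  nr <- nchar(rev_seq)
  if (min(nf, nr) < min_overlap) return(list(merged = FALSE))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  r_raw <- strsplit(rev_seq, "")[[1L]]
  r <- rev(unname(comp[r_raw]))
  rq <- rev(rev_qual)
  f <- strsplit(fwd_seq, "")[[1L]]
  cands <- data.frame(o = min_overlap:min(nf, nr))
  cands$mf <- vapply(cands$o, function(o) {
    mean(f[(nf - o + 1L):nf] != r[1:o])
  }, numeric(1))
  # lowest mismatch fraction, ties by longest overlap
  cands <- cands[order(cands$mf, -cands$o), ]
  best <- cands[1L, ]
  if (best$mf > max_mismatch_frac) return(list(merged = FALSE))
  o <- best$o
  fo <- (nf - o + 1L):nf
  cons <- character(o)
  consq <- integer(o)
  for (j in seq_len(o)) {
    fb <- f[fo[j]]; rb <- r[j]
    fq <- fwd_qual[fo[j]]; rqj <- rq[j]
    if (fb == rb) {
      cons[j] <- fb
      consq[j] <- max(fq, rqj)
    } else {
      cons[j] <- if (fq >= rqj) fb else rb
      consq[j] <- max(2L, abs(fq - rqj))
    }
  }
  r_tail <- if (nr > o) r[(o + 1L):nr] else character(0)
  q_tail <- if (nr > o) rq[(o + 1L):nr] else integer(0)
  list(merged = TRUE,
       seq = paste0(paste(f[seq_len(nf - o)], collapse = ""),
                    paste(cons, collapse = ""),
                    paste(r_tail, collapse = "")),
       qual = c(fwd_qual[seq_len(nf - o)], consq, q_tail),
       overlap = o, mismatch_frac = best$mf)
}

# --- exhaustive-breakpoint oracle for best_two_parent_model ----------------

oracle_two_parent <- function(query, profile_a, profile_b) {
  L <- nchar(query)
  best_c <- NA_integer_
  best_f <- -Inf
  for (c in 0:L) {
    f <- sum(profile_a[seq_len(c)]) +
      sum(profile_b[seq_len(L)[seq_len(L) > c]])
    if (f > best_f) {
      best_f <- f
      best_c <- c
    }
  }
  list(breakpoint = best_c, model_identity = 100 * best_f / L)
}

# --- brute-force first-fit oracle for cluster_greedy -----------------------

oracle_first_fit <- function(uniques, identity_threshold = 0.97,
                             max_errors = 7L) {
  n <- nrow(uniques)
  assign <- integer(n)
  cents <- character(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (ci in seq_along(cents)) {
      d <- mockamp:::pairwise_diffs(uniques$seq[i], cents[ci])
      if (d$identity >= 100 * identity_threshold &&
          d$n_errors <= max_errors) {
        hit <- ci
        break
      }
    }
    if (hit == 0L) {
      cents <- c(cents, uniques$seq[i])
      hit <- length(cents)
    }
    assign[i] <- hit
  }
  assign
}

# --- small simulation fixtures shared by several tests ---------------------

# synthetic strain panel with V4 amplicons and truth clusters assigned
make_panel <- function(seed = 20231L) {
  st0 <- synth_mock_strains(seed = seed)
  st <- extract_v4_all(st0)
  st <- assign_gc_clusters(st, overrides = attr(st0, "cluster_truth"))
  st
}

panel_refs <- function(st) {
  refs <- stats::setNames(st$v4_seq, st$strain_id)
  refs[!is.na(refs)]
}

# mutate k distinct positions of a sequence (test-local, independent of
# mockamp::mutate_seq)
mutate_at <- function(seq, pos) {
  s <- strsplit(seq, "")[[1L]]
  for (p in pos) {
    s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1L]
  }
  paste(s, collapse = "")
}
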