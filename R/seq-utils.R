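# Low-level nucleotide utilities shared across modules.

#' @keywords internal
.DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes -> base sets. U treated as T.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' GC content of a nucleotide sequence
#'
#' Percentage of G+C among unambiguous bases. `N` (and any other ambiguity
#' code) is excluded from both numerator and denominator.
#'
#' @param seq A single nucleotide string (A/C/G/T, N allowed).
#' @return GC content in percent, in `[0, 100]`.
#' @examples
#' gc_fraction("GGCC") # 100
#' gc_fraction("GANTC") # 50
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (nchar(seq) == 0L) stop("empty sequence")
  x <- gc_percent_vec(seq)
  if (is.na(x)) stop("sequence contains no unambiguous A/C/G/T bases")
  x
}

#' Vectorised GC percent
#'
#' Like [gc_fraction()] for many sequences; `NA` (instead of an error)
#' where a sequence has no unambiguous base.
#'
#' @param seqs Character vector of nucleotide strings.
#' @return Numeric vector of GC percentages.
#' @export
gc_percent_vec <- function(seqs) {
  up <- toupper(seqs)
  n_gc <- nchar(up) - nchar(gsub("[GC]", "", up))
  n_at <- nchar(up) - nchar(gsub("[AT]", "", up))
  tot <- n_gc + n_at
  ifelse(tot == 0L, NA_real_, 100 * n_gc / tot)
}

#' Reverse complement
#'
#' @param seq Character vector of nucleotide strings (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Find primer binding sites by IUPAC-aware window scan
#'
#' Scans every window of `seq` of the primer's length and reports those whose
#' IUPAC-compatible mismatch count is at most `max_mismatch`. A sequence base
#' matches a primer code iff it belongs to the code's base set (e.g. M =
#' \{A,C\}).
#'
#' @param seq Nucleotide string (forward strand).
#' @param primer Primer string, IUPAC codes allowed.
#' @param max_mismatch Maximum mismatches per window.
#' @return A data.frame with columns `position` (0-based start on `seq`) and
#'   `mismatches`, ascending by position. Empty when `seq` is shorter than
#'   the primer.
#' @export
match_primer <- function(seq, primer, max_mismatch = 2L) {
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(primer), length(primer) == 1L)
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  p <- strsplit(toupper(primer), "", fixed = TRUE)[[1L]]
  np <- length(p)
  ns <- length(s)
  if (np == 0L) stop("empty primer")
  if (ns < np) {
    return(data.frame(position = integer(0), mismatches = integer(0)))
  }
  nwin <- ns - np + 1L
  mism <- integer(nwin)
  for (i in seq_len(np)) {
    allowed <- .IUPAC[[p[i]]]
    if (is.null(allowed)) stop("unknown IUPAC code in primer: ", p[i])
    mism <- mism + !(s[i:(i + nwin - 1L)] %in% allowed)
  }
  hit <- which(mism <= max_mismatch)
  data.frame(position = hit - 1L, mismatches = mism[hit])
}

#' Random DNA sequences
#'
#' @param n Number of sequences.
#' @param len Length of each sequence (recycled).
#' @param gc Expected GC fraction in `[0, 1]`.
#' @return Character vector of length `n`.
#' @export
random_dna <- function(n, len, gc = 0.5) {
  len <- rep_len(len, n)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(len, function(l) {
    paste(sample(.DNA_BASES, l, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

# A sequence of length `len` with an exact number of G/C bases matching
# `gc_percent` as closely as base granularity allows.
seq_with_gc <- function(len, gc_percent) {
  n_gc <- round(len * gc_percent / 100)
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), len - n_gc, replace = TRUE))
  paste(sample(bases), collapse = "")
}

#' Substitute k random positions with a different base each
#'
#' @param seq Nucleotide string.
#' @param k Number of positions to change (capped at the length).
#' @return The mutated sequence.
#' @export
mutate_seq <- function(seq, k) {
  if (k == 0L) return(seq)
  n <- nchar(seq)
  pos <- sample.int(n, min(k, n))
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    ch[p] <- sample(setdiff(.DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Deterministic 31-bit child seed for independent RNG streams
#'
#' Used to decouple the PCR and sequencing random streams of a library and
#' to derive per-library seeds from a run seed.
#'
#' @param seed Parent integer seed.
#' @param stream Stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 1299721) %%
               2147483629)
}
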