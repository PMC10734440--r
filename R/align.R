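# Shared pairwise-alignment plumbing (Biostrings ends-free global alignment,
# match +1, mismatch -1, gap open -4, gap extend -1 per additional base).

.sub_matrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    }
    mat
  }
})

# Ends-free global alignment of many queries against one reference.
align_to_ref <- function(queries, ref) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(ref),
    type = "overlap", substitutionMatrix = .sub_matrix(),
    gapOpening = 3, gapExtension = 1
  )
}

# Identity of each query against one reference: 100 * matches / query length.
identity_to_ref <- function(queries, ref) {
  aln <- align_to_ref(queries, ref)
  100 * Biostrings::nmatch(aln) / nchar(queries)
}

# Per-query-position match indicator against a reference. Positions outside
# the aligned region, mismatches, and inserted query bases are FALSE.
match_profile <- function(query, ref) {
  aln <- align_to_ref(query, ref)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  prof <- logical(nchar(query))
  is_base <- p != "-"
  qpos <- Biostrings::start(Biostrings::pattern(aln)) - 1L + cumsum(is_base)
  hit <- is_base & p == s
  prof[qpos[hit]] <- TRUE
  prof
}

# Alignment operation summary between one query and one reference:
# matches, substitutions, insertions (query bases in reference gaps),
# deletions (reference bases in query gaps), within the aligned region.
alignment_ops <- function(p_chars, s_chars) {
  pb <- p_chars != "-"
  sb <- s_chars != "-"
  list(
    match = sum(pb & sb & p_chars == s_chars),
    sub = sum(pb & sb & p_chars != s_chars),
    ins = sum(pb & !sb),
    del = sum(!pb & sb)
  )
}

# Identity and error count used by OTU clustering: errors are substitutions
# plus gap bases within the aligned region; identity is matches over query
# length (unaligned query overhang counts against identity).
pairwise_diffs <- function(query, centroid) {
  aln <- align_to_ref(query, centroid)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ops <- alignment_ops(p, s)
  overhang <- nchar(query) - sum(p != "-")
  list(identity = 100 * ops$match / nchar(query),
       n_errors = ops$sub + ops$ins + ops$del + overhang)
}
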