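# Lightweight container for reads with per-base Phred qualities.

#' Construct a read set
#'
#' A `read_set` holds reads as parallel vectors: `id` (character), `seq`
#' (character) and `qual` (list of integer Phred vectors, one per read,
#' each the same length as its sequence).
#'
#' @param id Read identifiers.
#' @param seq Nucleotide strings.
#' @param qual List of integer quality vectors.
#' @return A `read_set` object.
#' @export
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (length(seq) > 0L && any(nchar(seq) != lengths(qual))) {
    stop("sequence and quality lengths differ")
  }
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = lapply(qual, as.integer)),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  read_set(x$id[i], x$seq[i], x$qual[i])
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "reads")
  if (length(x) > 0) {
    cat("; lengths", min(nchar(x$seq)), "-", max(nchar(x$seq)))
  }
  cat("\n")
  invisible(x)
}

#' Read and write FASTQ (Phred+33)
#'
#' @param path FASTQ file path.
#' @return `read_fastq` returns a [read_set()].
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping the (empty) metadata columns it
  # attaches to FASTQ imports; that metadata is not used here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  q <- suppressWarnings(as(Biostrings::quality(x), "IntegerList"))
  s <- suppressWarnings(as.character(x))
  read_set(names(x), s, as.list(q))
}

#' @rdname read_fastq
#' @param reads A [read_set()].
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  qual <- Biostrings::BStringSet(vapply(reads$qual, function(q) {
    rawToChar(as.raw(q + 33L))
  }, character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read / write FASTA
#'
#' @param path FASTA file path.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
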