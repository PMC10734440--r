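# Mock-community design: strains, V4 extraction by degenerate primers,
# GC clustering, and abundance tiers.

#' Universal V4 primers
#'
#' The 515F/806R primer pair targeting the V4 hypervariable region of the
#' bacterial 16S rRNA gene.
#' @format Character scalars.
#' @export
PRIMER_515F <- "GTGCCAGCMGCCGCGGTAA"

#' @rdname PRIMER_515F
#' @export
PRIMER_806R <- "GGACTACHVGGGTWTCTAAT"

#' Abundance tiers of the tiered mock communities
#'
#' Per-strain input percentages: high, medium and low tiers; the even design
#' uses 100/33 per strain instead.
#' @export
ABUNDANCE_TIERS <- c(high = 8.41, medium = 0.67, low = 0.01)

#' Construct a strain table
#'
#' A strain table is a data.frame with one row per mock-community strain and
#' columns `strain_id`, `phylum`, `full_seq`, and (after [extract_v4_all()]
#' and [assign_gc_clusters()]) `v4_seq`, `gc_percent`, `gc_cluster`,
#' `primer_mismatches_fwd`, `primer_mismatches_rev`, `amplifiable`.
#'
#' @param strain_id Character vector of unique strain identifiers.
#' @param full_seq Near full-length 16S sequences.
#' @param phylum Optional phylum labels.
#' @return A `strain_table` data.frame.
#' @export
strain_table <- function(strain_id, full_seq, phylum = NA_character_) {
  stopifnot(!anyDuplicated(strain_id), length(strain_id) == length(full_seq))
  df <- data.frame(
    strain_id = as.character(strain_id),
    phylum = rep_len(as.character(phylum), length(strain_id)),
    full_seq = toupper(full_seq),
    v4_seq = NA_character_,
    gc_percent = NA_real_,
    gc_cluster = NA_character_,
    primer_mismatches_fwd = NA_integer_,
    primer_mismatches_rev = NA_integer_,
    amplifiable = NA,
    stringsAsFactors = FALSE
  )
  class(df) <- c("strain_table", "data.frame")
  df
}

#' Extract the V4 amplicon of a sequence by primer matching
#'
#' Locates the forward primer on the forward strand and the reverse primer as
#' its reverse complement downstream of the forward site, taking for each the
#' site with fewest mismatches (ties: leftmost), and returns the insert
#' between (and excluding) the two primer sites.
#'
#' @param full_seq Nucleotide string.
#' @param fwd_primer,rev_primer Primer sequences (IUPAC); the reverse primer
#'   is given 5'->3' on the opposite strand, as conventionally written.
#' @param max_mismatch Maximum mismatches tolerated per primer site before
#'   the strain is flagged.
#' @param search_cap Mismatch cap used when searching for candidate sites
#'   (must be >= `max_mismatch`); sites worse than this are invisible.
#' @return A list with `v4` (string or `NA`), `fwd_mm`, `rev_mm`, and
#'   `status` in `"ok"`, `"primer_mismatch"`, `"no_site"`, `"orientation"`.
#' @export
extract_v4 <- function(full_seq, fwd_primer = PRIMER_515F,
                       rev_primer = PRIMER_806R, max_mismatch = 2L,
                       search_cap = max(max_mismatch, 4L)) {
  stopifnot(search_cap >= max_mismatch)
  fwd_hits <- match_primer(full_seq, fwd_primer, max_mismatch = search_cap)
  rev_site <- revcomp(rev_primer)
  rev_hits <- match_primer(full_seq, rev_site, max_mismatch = search_cap)
  if (nrow(fwd_hits) == 0L || nrow(rev_hits) == 0L) {
    return(list(v4 = NA_character_, fwd_mm = NA_integer_,
                rev_mm = NA_integer_, status = "no_site"))
  }
  fbest <- fwd_hits[order(fwd_hits$mismatches, fwd_hits$position), ][1L, ]
  # reverse site must lie fully downstream of the forward site
  fwd_end <- fbest$position + nchar(fwd_primer) # 0-based, exclusive
  rev_hits <- rev_hits[rev_hits$position >= fwd_end, , drop = FALSE]
  if (nrow(rev_hits) == 0L) {
    return(list(v4 = NA_character_, fwd_mm = fbest$mismatches,
                rev_mm = NA_integer_, status = "orientation"))
  }
  rbest <- rev_hits[order(rev_hits$mismatches, rev_hits$position), ][1L, ]
  insert <- substr(full_seq, fwd_end + 1L, rbest$position)
  status <- if (fbest$mismatches > max_mismatch ||
                rbest$mismatches > max_mismatch) "primer_mismatch" else "ok"
  list(v4 = if (status == "ok") insert else NA_character_,
       fwd_mm = fbest$mismatches, rev_mm = rbest$mismatches, status = status)
}

#' Extract V4 amplicons for every strain in a table
#'
#' Fills `v4_seq`, `gc_percent`, primer mismatch counts and the
#' `amplifiable` flag. Strains whose best primer site exceeds
#' `max_mismatch` stay in the table (they are the low-recovery strains) but
#' are flagged so the simulator can suppress their amplification.
#'
#' @inheritParams extract_v4
#' @param strains A [strain_table()].
#' @param keep_failed Keep the extracted insert for flagged strains so they
#'   can still be simulated at suppressed efficiency (default TRUE).
#' @return The strain table with amplicon columns filled.
#' @export
extract_v4_all <- function(strains, fwd_primer = PRIMER_515F,
                           rev_primer = PRIMER_806R, max_mismatch = 2L,
                           keep_failed = TRUE) {
  for (i in seq_len(nrow(strains))) {
    res <- extract_v4(strains$full_seq[i], fwd_primer, rev_primer,
                      max_mismatch = max_mismatch)
    v4 <- res$v4
    if (is.na(v4) && keep_failed && res$status == "primer_mismatch") {
      # recover the insert at the best (over-threshold) sites
      v4 <- extract_v4(strains$full_seq[i], fwd_primer, rev_primer,
                       max_mismatch = max(res$fwd_mm, res$rev_mm,
                                          na.rm = TRUE))$v4
    }
    strains$v4_seq[i] <- v4
    strains$gc_percent[i] <- if (is.na(v4)) NA_real_ else gc_fraction(v4)
    strains$primer_mismatches_fwd[i] <- res$fwd_mm
    strains$primer_mismatches_rev[i] <- res$rev_mm
    strains$amplifiable[i] <- res$status == "ok"
  }
  strains
}

#' Assign GC clusters by rank thirds
#'
#' Ranks strains by V4 GC content (ties broken by strain id) and assigns the
#' lowest third to `low`, the middle to `medium`, the highest to `high`. An
#' explicit override table (e.g. a published cluster membership) takes
#' precedence when supplied.
#'
#' @param strains A strain table with `gc_percent` computed.
#' @param overrides Optional named character vector `strain_id -> cluster`.
#' @return The strain table with `gc_cluster` set.
#' @export
assign_gc_clusters <- function(strains, overrides = NULL) {
  usable <- !is.na(strains$gc_percent)
  if (any(!usable)) {
    warning(sum(!usable), " strain(s) without a V4 amplicon excluded from ",
            "GC clustering")
  }
  n <- sum(usable)
  if (n %% 3L != 0L) stop("number of clusterable strains must be divisible by 3")
  idx <- which(usable)
  ord <- idx[order(strains$gc_percent[idx], strains$strain_id[idx])]
  third <- n %/% 3L
  cl <- rep(c("low", "medium", "high"), each = third)
  strains$gc_cluster <- NA_character_
  strains$gc_cluster[ord] <- cl
  if (!is.null(overrides)) {
    hit <- strains$strain_id %in% names(overrides)
    strains$gc_cluster[hit] <- unname(overrides[strains$strain_id[hit]])
  }
  strains
}

#' Build a mock-community design
#'
#' The even design assigns 100/33 % to each of the 33 strains; a tiered
#' design maps each GC cluster onto one of the input tiers 8.41 / 0.67 /
#' 0.01 %.
#'
#' @param strains A strain table with `gc_cluster` assigned.
#' @param mode `"even"` or `"tiered"`.
#' @param tier_map For tiered designs, a named numeric vector mapping each
#'   cluster (`low`, `medium`, `high`) onto a distinct tier value from
#'   [ABUNDANCE_TIERS].
#' @param design_name Label for the design (e.g. `"Bm1"`).
#' @return A `mock_design` object: list with `strains`,
#'   `expected_abundance` (named percent vector) and `design_name`.
#' @export
build_design <- function(strains, mode = c("even", "tiered"),
                         tier_map = NULL, design_name = NULL) {
  mode <- match.arg(mode)
  n <- nrow(strains)
  if (mode == "even") {
    if (n != 33L) warning("even design with ", n, " strains; using 100/n")
    ab <- rep(100 / n, n)
  } else {
    if (is.null(tier_map)) stop("tiered mode requires a tier_map")
    if (!setequal(names(tier_map), c("low", "medium", "high")) ||
        !setequal(round(unname(tier_map), 2), round(unname(ABUNDANCE_TIERS), 2))) {
      stop("tier_map must be a bijection of clusters onto tiers ",
           paste(ABUNDANCE_TIERS, collapse = "/"))
    }
    if (anyNA(strains$gc_cluster)) stop("tiered mode requires gc_cluster")
    ab <- unname(tier_map[strains$gc_cluster])
  }
  names(ab) <- strains$strain_id
  structure(list(strains = strains, expected_abundance = ab,
                 design_name = design_name %||%
                   if (mode == "even") "even" else "tiered",
                 mode = mode),
            class = "mock_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mock_design <- function(x, ...) {
  cat("Mock community design '", x$design_name, "' (", x$mode, ")\n", sep = "")
  cat("  strains:", nrow(x$strains), "\n")
  tab <- table(x$strains$gc_cluster)
  cat("  GC clusters:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  expected abundance sum:",
      format(sum(x$expected_abundance), digits = 6), "%\n")
  invisible(x)
}

#' The three study designs
#'
#' `design_bm1()` is the even community (3.03% per strain); `design_bm2()`
#' puts the low-GC cluster on the high-abundance tier (8.41%), the medium
#' cluster on 0.67% and the high-GC cluster on 0.01%; `design_bm3()` is the
#' reverse allotment (high-GC cluster on 8.41%).
#'
#' @param strains A strain table with clusters assigned.
#' @return A `mock_design`.
#' @export
design_bm1 <- function(strains) {
  build_design(strains, "even", design_name = "Bm1")
}

#' @rdname design_bm1
#' @export
design_bm2 <- function(strains) {
  build_design(strains, "tiered",
               tier_map = c(low = 8.41, medium = 0.67, high = 0.01),
               design_name = "Bm2")
}

#' @rdname design_bm1
#' @export
design_bm3 <- function(strains) {
  build_design(strains, "tiered",
               tier_map = c(low = 0.01, medium = 0.67, high = 8.41),
               design_name = "Bm3")
}

#' Read strain references from FASTA
#'
#' @param path FASTA file of near full-length 16S sequences.
#' @return A [strain_table()].
#' @export
read_strain_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  strain_table(names(x), as.character(x))
}

#' Write / read a mock design as TSV
#'
#' Columns: strain_id, phylum, gc_percent, gc_cluster, expected_percent,
#' primer mismatch counts and the amplifiable flag.
#'
#' @param design A `mock_design`.
#' @param path Output TSV path.
#' @export
write_design_tsv <- function(design, path) {
  df <- design$strains
  df$expected_percent <- design$expected_abundance[df$strain_id]
  df$full_seq <- NULL
  df$v4_seq <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
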