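# Dereplication, rarefaction, greedy 97% OTU clustering, unique-OTU
# flagging, and artifact classification.

#' Exact-string dereplication
#'
#' @param seqs Character vector of sequences.
#' @return A data.frame with `seq` and `abundance`, sorted by decreasing
#'   abundance, ties by lexicographic sequence order.
#' @export
dereplicate <- function(seqs) {
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(0), abundance = integer(0)))
  }
  tab <- table(seqs)
  df <- data.frame(seq = names(tab), abundance = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$abundance, df$seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Rarefy a library to a fixed depth
#'
#' Uniform subsampling without replacement, reproducible under `seed`.
#'
#' @param x Vector of reads (or read indices) of one library.
#' @param depth Number of reads to draw; the study depth was 5688 (the
#'   smallest library).
#' @param seed Integer seed.
#' @param library_id Label used in the error message.
#' @return A subsample of `x` of length `depth`.
#' @export
rarefy <- function(x, depth = 5688L, seed = 1L, library_id = "library") {
  if (depth > length(x)) {
    stop("rarefying depth ", depth, " exceeds size of ", library_id,
         " (", length(x), ")")
  }
  set.seed(seed)
  x[sample.int(length(x), depth)]
}

#' Greedy centroid OTU clustering at 97% identity
#'
#' Scans dereplicated uniques in decreasing abundance order; each unique
#' joins the first existing centroid to which it has identity at least
#' `identity_threshold` and at most `max_errors` differences (substitutions
#' plus gap bases), else founds a new centroid. Centroid sequences are
#' never updated.
#'
#' @param uniques A data.frame from [dereplicate()] (abundance-sorted).
#' @param identity_threshold Identity threshold as a fraction (0.97).
#' @param max_errors Maximum allowed differences (7, the 253-bp restatement
#'   of the 97% radius); both conditions are enforced conjunctively.
#' @return A list with `centroid` (integer vector mapping each unique to
#'   its OTU) and `otus` (data.frame `otu_id`, `representative`).
#' @export
cluster_greedy <- function(uniques, identity_threshold = 0.97,
                           max_errors = 7L) {
  n <- nrow(uniques)
  assign <- integer(n)
  cent_seq <- character(0)
  # exact k-mer screen: every query k-mer missing from a centroid overlaps
  # a query-side difference, so a centroid within max_errors differences
  # shares at least n_kmers - max_errors * k of the query's distinct
  # k-mers; centroids below that bound cannot satisfy the error condition
  # and are skipped without altering the first-fit partition
  k <- 8L
  kset <- function(s) {
    L <- nchar(s)
    if (L < k) character(0) else unique(substring(s, 1:(L - k + 1L), k:L))
  }
  cent_kmers <- list()
  for (i in seq_len(n)) {
    qk <- kset(uniques$seq[i])
    min_shared <- length(qk) - max_errors * k
    placed <- FALSE
    for (ci in seq_along(cent_seq)) {
      if (min_shared > 0L && sum(qk %in% cent_kmers[[ci]]) < min_shared) {
        next
      }
      d <- pairwise_diffs(uniques$seq[i], cent_seq[ci])
      if (d$identity >= 100 * identity_threshold &&
          d$n_errors <= max_errors) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cent_seq <- c(cent_seq, uniques$seq[i])
      cent_kmers[[length(cent_seq)]] <- kset(uniques$seq[i])
      assign[i] <- length(cent_seq)
    }
  }
  list(centroid = assign,
       otus = data.frame(otu_id = sprintf("OTU%04d", seq_along(cent_seq)),
                         representative = cent_seq,
                         stringsAsFactors = FALSE))
}

#' Build an OTU table from reads of several libraries
#'
#' Dereplicates all reads jointly, clusters the uniques greedily, and sums
#' member counts into an OTU x library matrix.
#'
#' @param seqs Character vector of reads (all libraries pooled).
#' @param library_ids Character vector parallel to `seqs`.
#' @inheritParams cluster_greedy
#' @return An `otu_table` object: list with `otus` (ids and representative
#'   sequences), `counts` (OTU x library integer matrix), `read_otu` (the
#'   OTU id of every input read, in input order), `flags` and
#'   `classification` (filled by [flag_unique_otus()] and
#'   [classify_artifacts()]).
#' @export
build_otu_table <- function(seqs, library_ids, identity_threshold = 0.97,
                            max_errors = 7L) {
  stopifnot(length(seqs) == length(library_ids))
  uniq <- dereplicate(seqs)
  cl <- cluster_greedy(uniq, identity_threshold, max_errors)
  libs <- sort(unique(library_ids))
  counts <- matrix(0L, nrow = nrow(cl$otus), ncol = length(libs),
                   dimnames = list(cl$otus$otu_id, libs))
  otu_of_read <- cl$centroid[match(seqs, uniq$seq)]
  for (j in seq_along(libs)) {
    t <- tabulate(otu_of_read[library_ids == libs[j]],
                  nbins = nrow(cl$otus))
    counts[, j] <- t
  }
  structure(list(otus = cl$otus, counts = counts,
                 read_otu = cl$otus$otu_id[otu_of_read], flags = NULL,
                 classification = NULL),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts),
      "libraries,", sum(x$counts), "reads\n")
  if (!is.null(x$classification)) {
    print(table(sub(":.*", "", x$classification)))
  }
  invisible(x)
}

#' Flag unique (spurious-candidate) OTUs
#'
#' OTUs with nonzero counts in exactly one technical replicate across all
#' libraries are flagged by their total count: `singleton` (1), `doubleton`
#' (2) or `other_unique` (>2); all remaining OTUs are `shared`.
#'
#' @param otu_table An `otu_table`.
#' @param replicate_map Named character vector mapping each library (column)
#'   to a replicate identity; defaults to one replicate per library.
#' @return The `otu_table` with `flags` filled (named character vector).
#' @export
flag_unique_otus <- function(otu_table, replicate_map = NULL) {
  counts <- otu_table$counts
  libs <- colnames(counts)
  if (is.null(replicate_map)) {
    replicate_map <- stats::setNames(libs, libs)
  }
  stopifnot(all(libs %in% names(replicate_map)))
  reps <- unique(unname(replicate_map[libs]))
  by_rep <- vapply(reps, function(r) {
    cols <- libs[replicate_map[libs] == r]
    rowSums(counts[, cols, drop = FALSE]) > 0
  }, logical(nrow(counts)))
  if (is.null(dim(by_rep))) by_rep <- matrix(by_rep, nrow = nrow(counts))
  n_reps <- rowSums(by_rep)
  total <- rowSums(counts)
  flags <- ifelse(n_reps != 1L, "shared",
                  ifelse(total == 1L, "singleton",
                         ifelse(total == 2L, "doubleton", "other_unique")))
  otu_table$flags <- stats::setNames(flags, rownames(counts))
  otu_table
}

#' Classify OTU representatives into strains and artifact classes
#'
#' Decision order per representative: (1) identity of at least
#' `true_match_threshold` to a mock strain and not chimeric: the strain;
#' (2) chimeric against the mock references: `chimera`; (3) at least 70%
#' identity to the external database and below 70% to the mock database:
#' `contaminant`; (4) at least 70% to the mock database: `erroneous`;
#' (5) otherwise `contaminant` (low confidence).
#'
#' @param otu_table An `otu_table`.
#' @param mock_refs Named character vector of mock strain amplicons.
#' @param db_refs Named character vector: external database.
#' @param mode Chimera detection mode.
#' @param true_match_threshold Identity (percent) for a true-strain call;
#'   97 by default, consistent with the OTU radius.
#' @param db_match_threshold Identity (percent) separating database matches
#'   from non-matches (70).
#' @return The `otu_table` with `classification` filled: values are
#'   `"true_strain:<id>"`, `"chimera"`, `"contaminant"`,
#'   `"contaminant_lowconf"` or `"erroneous"`.
#' @export
classify_artifacts <- function(otu_table, mock_refs, db_refs,
                               mode = c("balanced", "sensitive"),
                               true_match_threshold = 97,
                               db_match_threshold = 70) {
  mode <- match.arg(mode)
  reps <- otu_table$otus$representative
  mock_hit <- best_hit(reps, mock_refs)
  db_hit <- best_hit(reps, db_refs)
  chim <- classify_chimera(reps, mock_refs, mode = mode)$is_chimera
  cls <- character(length(reps))
  for (i in seq_along(reps)) {
    idm <- ifelse(is.na(mock_hit$identity[i]), 0, mock_hit$identity[i])
    ide <- ifelse(is.na(db_hit$identity[i]), 0, db_hit$identity[i])
    cls[i] <- if (idm >= true_match_threshold && !chim[i]) {
      paste0("true_strain:", mock_hit$ref_id[i])
    } else if (chim[i]) {
      "chimera"
    } else if (ide >= db_match_threshold && idm < db_match_threshold) {
      "contaminant"
    } else if (idm >= db_match_threshold) {
      "erroneous"
    } else {
      "contaminant_lowconf"
    }
  }
  otu_table$classification <- stats::setNames(cls, otu_table$otus$otu_id)
  otu_table
}

#' Decompose unique OTUs by artifact class
#'
#' Cross-tabulates the unique-OTU flags (singleton / doubleton /
#' other_unique) against the artifact classes, the machine-readable
#' analogue of a spurious-sequence composition table.
#'
#' @param otu_table An `otu_table` with flags and classification filled.
#' @return A contingency table (flags x classes).
#' @export
unique_otu_summary <- function(otu_table) {
  stopifnot(!is.null(otu_table$flags), !is.null(otu_table$classification))
  cls <- sub(":.*", "", otu_table$classification)
  table(flag = otu_table$flags, class = cls)
}
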