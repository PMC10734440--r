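# Reference-guided two-parent chimera detection and accounting.
#
# A query is modeled as a crossover of two reference parents: for every
# breakpoint c the model identity is the number of query positions matching
# parent A before c plus those matching parent B from c on, over the query
# length. A query is called chimeric when the best two-parent model is both
# good in absolute terms and sufficiently better than the best single
# reference.

# preset thresholds per detection mode
.chimera_mode <- function(mode) {
  switch(mode,
    balanced = list(delta = 2.0, id_min = 98.0),
    sensitive = list(delta = 1.0, id_min = 96.0),
    stop("unknown chimera mode: ", mode)
  )
}

# unique k-mer sets of each reference
.ref_kmers <- function(refs, k) {
  lapply(refs, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    unique(substring(r, 1:(n - k + 1L), k:n))
  })
}

# shared-k-mer count matrix (queries x references)
.kmer_share_matrix <- function(queries, refs, k) {
  ksets <- .ref_kmers(refs, k)
  m <- matrix(0L, nrow = length(queries), ncol = length(refs),
              dimnames = list(NULL, names(refs)))
  for (i in seq_along(queries)) {
    nq <- nchar(queries[i])
    if (nq < k) next
    qk <- unique(substring(queries[i], 1:(nq - k + 1L), k:nq))
    m[i, ] <- vapply(ksets, function(rk) sum(qk %in% rk), integer(1))
  }
  m
}

#' Candidate parents by shared k-mer count
#'
#' Ranks references by the number of distinct k-mers shared with the query
#' (ties by reference id) and returns the top `top_n`, always including the
#' reference with the best single identity when it is supplied.
#'
#' @param query Nucleotide string.
#' @param refs Named character vector of reference sequences.
#' @param k k-mer length.
#' @param top_n Number of candidates.
#' @param best_single Optional id of the best single-identity reference to
#'   force into the candidate set (computed internally when omitted).
#' @return Character vector of reference ids.
#' @export
find_parent_candidates <- function(query, refs, k = 8L, top_n = 4L,
                                   best_single = NULL) {
  stopifnot(length(refs) > 0L)
  nq <- nchar(query)
  if (nq >= k) {
    qk <- unique(substring(query, 1:(nq - k + 1L), k:nq))
    shared <- vapply(.ref_kmers(refs, k), function(rk) {
      sum(qk %in% rk)
    }, numeric(1))
  } else {
    shared <- stats::setNames(rep(0, length(refs)), names(refs))
  }
  if (all(shared == 0)) {
    # degenerate: fall back to identity ranking
    ids <- vapply(refs, function(r) identity_to_ref(query, r), numeric(1))
    ord <- order(-ids, names(refs))
  } else {
    ord <- order(-shared, names(refs))
  }
  cand <- names(refs)[ord][seq_len(min(top_n, length(refs)))]
  if (is.null(best_single)) {
    ids <- vapply(refs, function(r) identity_to_ref(query, r), numeric(1))
    best_single <- names(refs)[order(-ids, names(refs))][1L]
  }
  union(cand, best_single)
}

#' Best two-parent crossover model for a query
#'
#' @param query Nucleotide string.
#' @param parent_a,parent_b Parent reference sequences (prefix parent and
#'   suffix parent).
#' @param profile_a,profile_b Optional precomputed [match_profile()]s.
#' @return List with `breakpoint` (0-based query coordinate of the first
#'   position attributed to parent B; smallest on ties) and
#'   `model_identity` in percent.
#' @export
best_two_parent_model <- function(query, parent_a, parent_b,
                                  profile_a = NULL, profile_b = NULL) {
  if (is.null(profile_a)) profile_a <- match_profile(query, parent_a)
  if (is.null(profile_b)) profile_b <- match_profile(query, parent_b)
  L <- nchar(query)
  pa <- c(0, cumsum(profile_a)) # matches of A on [0, c)
  sb <- rev(c(0, cumsum(rev(profile_b)))) # matches of B on [c, L)
  f <- pa + sb # indexed by c = 0..L
  c_best <- which.max(f) - 1L
  list(breakpoint = c_best, model_identity = 100 * f[c_best + 1L] / L)
}

#' Classify sequences as chimeric against a reference set
#'
#' @param queries Character vector of (typically dereplicated) sequences.
#' @param refs Named character vector of reference sequences.
#' @param mode `"balanced"` (identity gain >= 2, model identity >= 98) or
#'   `"sensitive"` (gain >= 1, model identity >= 96).
#' @param k,top_n Candidate-search parameters (see
#'   [find_parent_candidates()]).
#' @param reference_set Label recorded on the calls (`"mock"` or
#'   `"database"`).
#' @param prescreen_n With more than `prescreen_n` references, single
#'   identities are evaluated only for the `prescreen_n` references sharing
#'   the most k-mers with the query (the best single reference is taken from
#'   that set); with `prescreen_n` references or fewer, all references are
#'   evaluated exactly.
#' @return A data.frame of chimera calls: `query` (index), `is_chimera`,
#'   `parent_a`, `parent_b`, `breakpoint`, `best_single_identity`,
#'   `best_model_identity`, `mode`, `reference_set`.
#' @export
classify_chimera <- function(queries, refs, mode = c("balanced", "sensitive"),
                             k = 8L, top_n = 4L, reference_set = "mock",
                             prescreen_n = 8L) {
  mode <- match.arg(mode)
  thr <- .chimera_mode(mode)
  stopifnot(length(refs) > 0L, prescreen_n >= top_n)
  refs <- refs[order(names(refs))]
  nq <- length(queries)
  nref <- length(refs)
  share <- if (nq > 0L) .kmer_share_matrix(queries, refs, k) else
    matrix(0L, 0L, nref)
  # per-query prescreen set, ordered by decreasing shared k-mers (ties by
  # reference id); degenerate rows (no shared k-mers) keep all references
  pres_list <- vector("list", nq)
  for (i in seq_len(nq)) {
    sh <- share[i, ]
    if (nref <= prescreen_n || all(sh == 0)) {
      pres_list[[i]] <- names(refs)
    } else {
      ord <- order(-sh, names(refs))
      pres_list[[i]] <- names(refs)[ord][seq_len(prescreen_n)]
    }
  }
  # single identities: one vectorised alignment call per needed reference
  idmat <- matrix(NA_real_, nrow = nq, ncol = nref,
                  dimnames = list(NULL, names(refs)))
  need_id <- split(rep(seq_len(nq), lengths(pres_list)), unlist(pres_list))
  for (rid in names(need_id)) {
    qi <- need_id[[rid]]
    idmat[qi, rid] <- identity_to_ref(queries[qi], refs[[rid]])
  }
  out <- data.frame(
    query = seq_len(nq), is_chimera = logical(nq),
    parent_a = NA_character_, parent_b = NA_character_,
    breakpoint = NA_integer_, best_single_identity = 0,
    best_model_identity = 0, mode = mode, reference_set = reference_set,
    stringsAsFactors = FALSE
  )
  # candidate parents per query
  cand_list <- vector("list", nq)
  for (i in seq_len(nq)) {
    pres <- pres_list[[i]]
    idr <- idmat[i, pres]
    by_id <- pres[order(-idr, pres)]
    out$best_single_identity[i] <- idmat[i, by_id[1L]]
    ord_names <- if (all(share[i, ] == 0)) by_id else pres
    cand_list[[i]] <- union(ord_names[seq_len(min(top_n,
                                                  length(ord_names)))],
                            by_id[1L])
  }
  # one vectorised alignment call per reference for all queries needing it
  prof_list <- lapply(seq_len(nq), function(i) list())
  need <- split(rep(seq_len(nq), lengths(cand_list)), unlist(cand_list))
  for (rid in names(need)) {
    qi <- need[[rid]]
    aln <- align_to_ref(queries[qi], refs[[rid]])
    pats <- as.character(Biostrings::alignedPattern(aln))
    subs <- as.character(Biostrings::alignedSubject(aln))
    p_start <- Biostrings::start(Biostrings::pattern(aln))
    for (t in seq_along(qi)) {
      p <- strsplit(pats[t], "", fixed = TRUE)[[1L]]
      s <- strsplit(subs[t], "", fixed = TRUE)[[1L]]
      prof <- logical(nchar(queries[qi[t]]))
      is_base <- p != "-"
      qpos <- p_start[t] - 1L + cumsum(is_base)
      hit <- is_base & p == s
      prof[qpos[hit]] <- TRUE
      prof_list[[qi[t]]][[rid]] <- prof
    }
  }
  for (i in seq_len(nq)) {
    q <- queries[i]
    best_single <- out$best_single_identity[i]
    cand <- cand_list[[i]]
    if (length(cand) < 2L) {
      out$best_model_identity[i] <- best_single
      next
    }
    profiles <- prof_list[[i]][cand]
    best <- list(model_identity = -Inf)
    best_pair <- c(NA_character_, NA_character_)
    for (a in cand) {
      for (b in cand) {
        if (a == b) next
        m <- best_two_parent_model(q, NULL, NULL, profiles[[a]],
                                   profiles[[b]])
        better <- m$model_identity > best$model_identity ||
          (m$model_identity == best$model_identity &&
             (is.na(best_pair[1L]) || a < best_pair[1L] ||
                (a == best_pair[1L] && b < best_pair[2L])))
        if (better) {
          best <- m
          best_pair <- c(a, b)
        }
      }
    }
    out$best_model_identity[i] <- max(best$model_identity, best_single)
    gain <- out$best_model_identity[i] - best_single
    if (out$best_model_identity[i] >= thr$id_min && gain >= thr$delta) {
      out$is_chimera[i] <- TRUE
      out$parent_a[i] <- best_pair[1L]
      out$parent_b[i] <- best_pair[2L]
      out$breakpoint[i] <- best$breakpoint
    }
  }
  out
}

#' Chimera accounting against dual reference sets
#'
#' Classifies reads (via their dereplicated unique sequences) against the
#' mock-community references (the "true" chimeras) and against an external
#' database (the "detected" chimeras); undetected chimeras are the true set
#' minus the detected set.
#'
#' @param seqs Character vector of merged read sequences.
#' @param mock_refs Named character vector: the mock strain amplicons.
#' @param db_refs Named character vector: the external database.
#' @param mode Chimera mode for both classifications.
#' @param read_ids Optional read identifiers (defaults to positions).
#' @return A list of class `chimera_accounting`: `n_reads`, `n_true`,
#'   `n_detected`, `n_undetected`, the corresponding `rate_*` percentages
#'   (of all reads), per-read logical vectors `true_chimera` /
#'   `detected_chimera`, and `gc_summary` (mean GC of chimeric vs
#'   non-chimeric reads by the truth-mode call).
#' @export
chimera_accounting <- function(seqs, mock_refs, db_refs,
                               mode = c("balanced", "sensitive"),
                               read_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(mock_refs) > 0L, length(db_refs) > 0L)
  n <- length(seqs)
  if (is.null(read_ids)) read_ids <- as.character(seq_len(n))
  uniq <- dereplicate(seqs)
  map <- match(seqs, uniq$seq)
  true_u <- classify_chimera(uniq$seq, mock_refs, mode = mode,
                             reference_set = "mock")$is_chimera
  det_u <- classify_chimera(uniq$seq, db_refs, mode = mode,
                            reference_set = "database")$is_chimera
  true_r <- true_u[map]
  det_r <- det_u[map]
  undet_r <- true_r & !det_r
  gc <- gc_percent_vec(seqs)
  res <- list(
    n_reads = n, n_true = sum(true_r), n_detected = sum(det_r),
    n_undetected = sum(undet_r),
    rate_true = if (n > 0) 100 * sum(true_r) / n else NA_real_,
    rate_detected = if (n > 0) 100 * sum(det_r) / n else NA_real_,
    rate_undetected = if (n > 0) 100 * sum(undet_r) / n else NA_real_,
    true_chimera = stats::setNames(true_r, read_ids),
    detected_chimera = stats::setNames(det_r, read_ids),
    gc_summary = c(chimeric = mean(gc[true_r]),
                   non_chimeric = mean(gc[!true_r])),
    mode = mode
  )
  class(res) <- "chimera_accounting"
  res
}

#' @export
print.chimera_accounting <- function(x, ...) {
  cat(sprintf(
    "Chimera accounting (%s mode): %d reads; true %.2f%%, detected %.2f%%, undetected %.2f%%\n",
    x$mode, x$n_reads, x$rate_true, x$rate_detected, x$rate_undetected))
  invisible(x)
}
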