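# PCR + sequencing simulator with ground-truth labels.
#
# Mechanistic model: per cycle every template is copied with a
# strain-dependent efficiency; copies acquire polymerase substitutions; a
# fraction of copies abort at a uniform position, entering a pool of
# incomplete-extension fragments; in later cycles each fragment re-anneals
# to a template with a probability that increases with the fragment's GC
# content (a free-energy proxy) and with the saturation of the reaction
# (product concentration relative to the pool cap), and is extended into a
# two-parent product whose breakpoint is the fragment end. Re-annealing
# within the same strain yields a self-chimera, indistinguishable from a
# normal product and labeled origin = "strain". A two-step protocol starts
# its second PCR from a diluted aliquot with fresh reagents, which resets
# both the fragment pool and the saturation level; chimeras therefore
# accumulate mostly in late, saturated cycles of long single-step runs.

#' Simulation parameters
#'
#' @param protocol `"one_step"` (a single PCR) or `"two_step"` (a first PCR
#'   with target-only primers followed by a second PCR started from a
#'   diluted aliquot with fresh reagents, which resets the
#'   incomplete-fragment pool and the reaction's saturation level).
#' @param cycles_step1,cycles_step2 Cycle counts (35 and 0 for one-step;
#'   10 and 20 for the two-step default). Each must be <= 35.
#' @param p_amp Per-cycle duplication probability of an unimpaired template.
#' @param primer_mismatch_penalty Multiplicative amplification penalty per
#'   forward-primer mismatch of a strain.
#' @param pol_error_rate Substitution probability per base per copy event.
#' @param incomplete_ext_prob Probability that a copy aborts, producing an
#'   incomplete-extension fragment.
#' @param chimera_gc_coeffs Logistic coefficients `c(a, b)`: a fragment with
#'   GC fraction g re-anneals with probability `plogis(a + b * g)`; `b > 0`
#'   encodes the stronger duplex binding of GC-rich fragments.
#' @param contaminant_rate Probability that a final molecule is replaced by
#'   a contaminant amplicon (see [inject_contaminants()]).
#' @param read_length Sequencer read length in bases.
#' @param qual_decay_fwd,qual_decay_rev Expected Phred quality at the first
#'   and last read position for the forward and reverse mate; quality
#'   follows a convex decay between them, dropping fastest toward the read
#'   end (reverse reads decay more).
#' @param qual_sd Gaussian jitter of per-base quality around the curve.
#' @param crosstalk_bias Probability that a miscall stays within its
#'   fluorophore pair (A<->C or G<->T) rather than landing uniformly on the
#'   other two bases.
#' @param spacer_fwd,spacer_rev Phasing-spacer lengths consumed at the start
#'   of the forward and reverse read; they must sum to 7 when phasing is in
#'   use, or both be 0 (non-phasing).
#' @param n_init Initial number of template molecules.
#' @param pool_cap,frag_cap Molecule caps for the template and fragment
#'   pools; pools exceeding the cap are down-sampled (a dilution that
#'   preserves composition).
#' @param seed Integer seed; PCR and sequencing use independent RNG streams
#'   derived from it.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(protocol = c("one_step", "two_step"),
                       cycles_step1 = NULL, cycles_step2 = NULL,
                       p_amp = 0.9, primer_mismatch_penalty = 0.1,
                       pol_error_rate = 2e-5, incomplete_ext_prob = 0.005,
                       chimera_gc_coeffs = c(a = -3, b = 4),
                       contaminant_rate = 0, read_length = 250L,
                       qual_decay_fwd = c(38, 25),
                       qual_decay_rev = c(37, 16), qual_sd = 2,
                       crosstalk_bias = 0.8, spacer_fwd = 0L,
                       spacer_rev = 0L, n_init = 2000L, pool_cap = 12000L,
                       frag_cap = 6000L, seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(cycles_step1)) {
    cycles_step1 <- if (protocol == "one_step") 35L else 10L
  }
  if (is.null(cycles_step2)) {
    cycles_step2 <- if (protocol == "one_step") 0L else 20L
  }
  p <- list(protocol = protocol, cycles_step1 = as.integer(cycles_step1),
            cycles_step2 = as.integer(cycles_step2), p_amp = p_amp,
            primer_mismatch_penalty = primer_mismatch_penalty,
            pol_error_rate = pol_error_rate,
            incomplete_ext_prob = incomplete_ext_prob,
            chimera_gc_coeffs = chimera_gc_coeffs,
            contaminant_rate = contaminant_rate,
            read_length = as.integer(read_length),
            qual_decay_fwd = qual_decay_fwd, qual_decay_rev = qual_decay_rev,
            qual_sd = qual_sd, crosstalk_bias = crosstalk_bias,
            spacer_fwd = as.integer(spacer_fwd),
            spacer_rev = as.integer(spacer_rev),
            n_init = as.integer(n_init), pool_cap = as.integer(pool_cap),
            frag_cap = as.integer(frag_cap), seed = as.integer(seed))
  probs <- c(p$p_amp, p$primer_mismatch_penalty, p$pol_error_rate,
             p$incomplete_ext_prob, p$contaminant_rate, p$crosstalk_bias)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$cycles_step1 > 35L || p$cycles_step2 > 35L) {
    stop("cycles per step must be <= 35")
  }
  if (p$protocol == "one_step" && p$cycles_step2 > 0L) {
    stop("one-step protocol has no second-step cycles")
  }
  sp <- p$spacer_fwd + p$spacer_rev
  if (!(sp == 0L || sp == 7L)) {
    stop("spacer lengths must be 0/0 (non-phasing) or sum to 7 (phasing)")
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (", x$protocol, ", ",
      x$cycles_step1, if (x$cycles_step2 > 0) paste0("+", x$cycles_step2),
      " cycles, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Method presets
#'
#' Parameter presets for the three library-preparation methods: non-phasing
#' (one-step, no spacers), one-step phasing and two-step phasing (10 + 20
#' cycles, fresh reagents in the second step).
#'
#' @param method One of `"non_phasing"`, `"one_step_phasing"`,
#'   `"two_step_phasing"`.
#' @param spacer_fwd Forward spacer length (0-7) for the phasing methods;
#'   the reverse spacer is `7 - spacer_fwd`.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
method_params <- function(method = c("non_phasing", "one_step_phasing",
                                     "two_step_phasing"),
                          spacer_fwd = 0L, ...) {
  method <- match.arg(method)
  switch(method,
    non_phasing = sim_params(protocol = "one_step", spacer_fwd = 0L,
                             spacer_rev = 0L, ...),
    one_step_phasing = sim_params(protocol = "one_step",
                                  spacer_fwd = spacer_fwd,
                                  spacer_rev = 7L - spacer_fwd, ...),
    two_step_phasing = sim_params(protocol = "two_step",
                                  spacer_fwd = spacer_fwd,
                                  spacer_rev = 7L - spacer_fwd, ...)
  )
}

# down-sample a pool (list of parallel vectors) to at most `cap` molecules
.cap_pool <- function(pool, cap) {
  n <- length(pool$seq)
  if (n <= cap) return(pool)
  keep <- sample.int(n, cap)
  lapply(pool, `[`, keep)
}

.empty_pool <- function() {
  list(seq = character(0), parent_a = character(0),
       parent_b = character(0), breakpoint = integer(0),
       n_subs = integer(0))
}

#' Simulate PCR amplification of a mock community
#'
#' Runs the per-cycle amplification model (see the package vignette) and
#' returns `n_final` labeled product molecules.
#'
#' @param design A `mock_design` whose strains carry `v4_seq`.
#' @param params A [sim_params()] object.
#' @param n_final Number of molecules to draw from the final pool.
#' @return A `sim_pool` data.frame with columns `seq`, `origin` (`strain` or
#'   `chimera`), `parent_a`, `parent_b`, `breakpoint` (0-based first
#'   position from parent_b), `n_pcr_subs`.
#' @export
simulate_pcr <- function(design, params, n_final) {
  stopifnot(inherits(design, "mock_design"), inherits(params, "sim_params"),
            n_final >= 1)
  set.seed(derive_seed(params$seed, 1L))
  st <- design$strains
  ok <- !is.na(st$v4_seq)
  ids <- st$strain_id[ok]
  amp <- stats::setNames(st$v4_seq[ok], ids)
  mm <- stats::setNames(ifelse(is.na(st$primer_mismatches_fwd[ok]), 0L,
                               st$primer_mismatches_fwd[ok]), ids)
  eff <- stats::setNames(params$p_amp *
                           params$primer_mismatch_penalty ^ mm[ids], ids)
  w <- design$expected_abundance[ids]
  init_counts <- stats::rmultinom(1, params$n_init, w / sum(w))[, 1]
  tpl <- list(
    seq = unname(rep(amp[ids], init_counts)),
    parent_a = rep(ids, init_counts),
    parent_b = rep(NA_character_, sum(init_counts)),
    breakpoint = rep(NA_integer_, sum(init_counts)),
    n_subs = integer(sum(init_counts))
  )
  frag <- list(seq = character(0), parent = character(0), n_subs = integer(0))
  a <- params$chimera_gc_coeffs[[1]]
  b <- params$chimera_gc_coeffs[[2]]
  run_step <- function(tpl, frag, n_cycles) {
    for (cyc in seq_len(n_cycles)) {
      # fragment re-annealing and extension into two-parent products
      nf <- length(frag$seq)
      if (nf > 0L) {
        saturation <- min(1, length(tpl$seq) / params$pool_cap)
        p_re <- saturation *
          stats::plogis(a + b * gc_percent_vec(frag$seq) / 100)
        re <- stats::runif(nf) < p_re
        pure <- which(is.na(tpl$parent_b))
        if (any(re) && length(pure) > 0L) {
          ri <- which(re)
          tmpl <- pure[sample.int(length(pure), length(ri), replace = TRUE)]
          bp <- nchar(frag$seq[ri])
          usable <- bp < nchar(tpl$seq[tmpl])
          ri <- ri[usable]; tmpl <- tmpl[usable]; bp <- bp[usable]
          if (length(ri) > 0L) {
            prod_seq <- paste0(frag$seq[ri],
                               substring(tpl$seq[tmpl], bp + 1L))
            pa <- frag$parent[ri]
            pb <- tpl$parent_a[tmpl]
            self <- pa == pb
            tpl$seq <- c(tpl$seq, prod_seq)
            tpl$parent_a <- c(tpl$parent_a, pa)
            tpl$parent_b <- c(tpl$parent_b,
                              ifelse(self, NA_character_, pb))
            tpl$breakpoint <- c(tpl$breakpoint,
                                ifelse(self, NA_integer_, bp))
            tpl$n_subs <- c(tpl$n_subs,
                            frag$n_subs[ri] + tpl$n_subs[tmpl])
          }
          keep <- setdiff(seq_len(nf), which(re))
          frag <- lapply(frag, `[`, keep)
        }
      }
      # duplication with polymerase errors and incomplete extension
      nt <- length(tpl$seq)
      p_dup <- ifelse(is.na(tpl$parent_b), eff[tpl$parent_a], params$p_amp)
      dup <- which(stats::runif(nt) < p_dup)
      if (length(dup) > 0L) {
        cp_seq <- tpl$seq[dup]
        nsub <- stats::rbinom(length(dup), nchar(cp_seq),
                              params$pol_error_rate)
        for (j in which(nsub > 0L)) {
          cp_seq[j] <- mutate_seq(cp_seq[j], nsub[j])
        }
        abort <- stats::runif(length(dup)) < params$incomplete_ext_prob
        full <- which(!abort)
        if (length(full) > 0L) {
          tpl$seq <- c(tpl$seq, cp_seq[full])
          tpl$parent_a <- c(tpl$parent_a, tpl$parent_a[dup[full]])
          tpl$parent_b <- c(tpl$parent_b, tpl$parent_b[dup[full]])
          tpl$breakpoint <- c(tpl$breakpoint, tpl$breakpoint[dup[full]])
          tpl$n_subs <- c(tpl$n_subs, tpl$n_subs[dup[full]] + nsub[full])
        }
        # only fragments of pure (single-parent) copies are tracked, so
        # every chimera remains a single-breakpoint two-parent product
        ab <- which(abort & is.na(tpl$parent_b[dup]))
        if (length(ab) > 0L) {
          len <- nchar(cp_seq[ab])
          cut <- vapply(len, function(l) sample.int(l - 1L, 1L), integer(1))
          frag$seq <- c(frag$seq, substring(cp_seq[ab], 1L, cut))
          frag$parent <- c(frag$parent, tpl$parent_a[dup[ab]])
          frag$n_subs <- c(frag$n_subs, tpl$n_subs[dup[ab]] + nsub[ab])
        }
      }
      tpl <- .cap_pool(tpl, params$pool_cap)
      frag <- .cap_pool(frag, params$frag_cap)
    }
    list(tpl = tpl, frag = frag)
  }
  res <- run_step(tpl, frag, params$cycles_step1)
  if (params$protocol == "two_step" && params$cycles_step2 > 0L) {
    # second PCR from a diluted aliquot with fresh reagents: the
    # incomplete-fragment pool does not carry over and saturation restarts
    res <- run_step(.cap_pool(res$tpl, params$n_init),
                    list(seq = character(0), parent = character(0),
                         n_subs = integer(0)), params$cycles_step2)
  }
  tpl <- res$tpl
  n_pool <- length(tpl$seq)
  if (n_final > n_pool) {
    warning("n_final (", n_final, ") exceeds pool size (", n_pool,
            "); sampling with replacement")
    pick <- sample.int(n_pool, n_final, replace = TRUE)
  } else {
    pick <- sample.int(n_pool, n_final)
  }
  out <- data.frame(
    seq = tpl$seq[pick],
    origin = ifelse(is.na(tpl$parent_b[pick]), "strain", "chimera"),
    parent_a = tpl$parent_a[pick],
    parent_b = tpl$parent_b[pick],
    breakpoint = tpl$breakpoint[pick],
    n_pcr_subs = tpl$n_subs[pick],
    stringsAsFactors = FALSE
  )
  class(out) <- c("sim_pool", "data.frame")
  attr(out, "params") <- params
  out
}

#' Replace a fraction of a pool by contaminant molecules
#'
#' @param pool A `sim_pool` from [simulate_pcr()].
#' @param contaminants Named character vector of contaminant amplicons.
#' @param rate Per-molecule replacement probability.
#' @return The modified pool; replaced rows have `origin = "contaminant"`.
#' @export
inject_contaminants <- function(pool, contaminants, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(pool)
  if (length(contaminants) == 0L) {
    stop("contaminant_rate > 0 but no contaminant sequences supplied")
  }
  hit <- which(stats::runif(nrow(pool)) < rate)
  if (length(hit) > 0L) {
    ci <- sample.int(length(contaminants), length(hit), replace = TRUE)
    pool$seq[hit] <- unname(contaminants[ci])
    pool$origin[hit] <- "contaminant"
    pool$parent_a[hit] <- names(contaminants)[ci]
    pool$parent_b[hit] <- NA_character_
    pool$breakpoint[hit] <- NA_integer_
    pool$n_pcr_subs[hit] <- 0L
  }
  pool
}

# convex expected-quality curve over read positions: stays near the start
# quality and decays toward the end quality, dropping fastest near the end
# of the read (the characteristic sequencing-by-synthesis shape)
.qual_curve <- function(decay, read_length, len, shape = 6) {
  t <- (seq_len(read_length) - 1L) / max(read_length - 1L, 1L)
  q <- decay[2] + (decay[1] - decay[2]) * (1 - t ^ shape)
  q[seq_len(len)]
}

.CROSSTALK_PARTNER <- c(A = "C", C = "A", G = "T", T = "G")

# sequence one mate: returns list(seq, qual, n_miscalls)
.sequence_mate <- function(template, decay, params) {
  len <- nchar(template)
  qmean <- .qual_curve(decay, params$read_length, len)
  q <- as.integer(pmin(41, pmax(2, round(qmean +
                                           stats::rnorm(len, 0, params$qual_sd)))))
  p_err <- 10 ^ (-q / 10)
  ch <- strsplit(template, "", fixed = TRUE)[[1L]]
  err <- which(stats::runif(len) < p_err)
  for (i in err) {
    if (stats::runif(1) < params$crosstalk_bias) {
      ch[i] <- .CROSSTALK_PARTNER[[ch[i]]]
    } else {
      ch[i] <- sample(setdiff(.DNA_BASES,
                              c(ch[i], .CROSSTALK_PARTNER[[ch[i]]])), 1L)
    }
  }
  list(seq = paste(ch, collapse = ""), qual = q, n_miscalls = length(err))
}

#' Simulate paired-end sequencing of a product pool
#'
#' The forward read covers the 5' end of each molecule and the reverse read
#' the reverse complement of its 3' end. Phasing spacers consume read cycles,
#' shortening the effective insert coverage. Per-base qualities are drawn
#' around a decaying curve (reverse worse than forward) and each
#' base is miscalled with probability `10^(-Q/10)`; miscalls fall on the
#' fluorophore partner (A<->C, G<->T) with probability `crosstalk_bias`.
#' The expected quality follows the convex [sim_params()] decay curve
#' (near-constant early, dropping toward the read end).
#'
#' @param pool A `sim_pool` (optionally after [inject_contaminants()]).
#' @param params A [sim_params()] object.
#' @param library_id Library label recorded in the truth table.
#' @return A list with `fwd` and `rev` [read_set()]s and `truth`, a
#'   data.frame with one row per read pair (`read_id`, `origin`,
#'   `parent_a`, `parent_b`, `breakpoint`, `n_pcr_substitutions`,
#'   `n_seq_substitutions`, `library_id`).
#' @export
simulate_reads <- function(pool, params, library_id = "lib1") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 2L))
  n <- nrow(pool)
  len_f <- params$read_length - params$spacer_fwd
  len_r <- params$read_length - params$spacer_rev
  ids <- sprintf("%s_read%05d", library_id, seq_len(n))
  fseq <- character(n); rseq <- character(n)
  fq <- vector("list", n); rq <- vector("list", n)
  nmis <- integer(n)
  for (i in seq_len(n)) {
    mol <- pool$seq[i]
    L <- nchar(mol)
    f_tpl <- substr(mol, 1L, min(len_f, L))
    r_tpl <- revcomp(substr(mol, max(1L, L - len_r + 1L), L))
    f <- .sequence_mate(f_tpl, params$qual_decay_fwd, params)
    r <- .sequence_mate(r_tpl, params$qual_decay_rev, params)
    fseq[i] <- f$seq; fq[[i]] <- f$qual
    rseq[i] <- r$seq; rq[[i]] <- r$qual
    nmis[i] <- f$n_miscalls + r$n_miscalls
  }
  truth <- data.frame(
    read_id = ids, origin = pool$origin, parent_a = pool$parent_a,
    parent_b = pool$parent_b, breakpoint = pool$breakpoint,
    n_pcr_substitutions = pool$n_pcr_subs, n_seq_substitutions = nmis,
    library_id = library_id, stringsAsFactors = FALSE
  )
  list(fwd = read_set(ids, fseq, fq), rev = read_set(ids, rseq, rq),
       truth = truth)
}

#' Write / read a truth sidecar table
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param path TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
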