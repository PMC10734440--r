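# End-to-end orchestration: run configuration, the simulate and evaluate
# subcommands, and the TSV report bundle.

#' Run configuration
#'
#' Builds the configuration consumed by [run_simulate()] and
#' [run_evaluate()]: defaults, optionally overridden by a YAML file, then by
#' `...`. The configuration round-trips losslessly through
#' [write_run_config()] / `run_config(path)`.
#'
#' @param path Optional YAML file of overrides.
#' @param ... Named overrides applied last.
#' @return A `run_config` list. Fields: `communities`, `methods`,
#'   `replicates`, `n_final` (reads per library), `contaminant_rate`,
#'   `seed`, `strain_seed`, `trim_grid`, `eval_trim_level` (level used for
#'   the merged reads entering chimera/OTU analysis), `chimera_mode`,
#'   `rarefy_depth` (NULL disables rarefaction), `rarefy_seed`,
#'   `max_error_reads` (per-stratum alignment cap of the error grid),
#'   `error_grid_replicate` (replicate whose libraries enter the error
#'   grid), `identity_threshold`, `max_errors`, `min_len`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    communities = c("Bm1", "Bm2", "Bm3"),
    methods = c("non_phasing", "one_step_phasing", "two_step_phasing"),
    replicates = 2L,
    n_final = 300L,
    contaminant_rate = 0.01,
    seed = 1L,
    strain_seed = 20231L,
    trim_grid = TRIM_GRID,
    eval_trim_level = "raw",
    chimera_mode = "balanced",
    rarefy_depth = NULL,
    rarefy_seed = 1L,
    max_error_reads = 150L,
    error_grid_replicate = 1L,
    identity_threshold = 0.97,
    max_errors = 7L,
    min_len = 200L
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    over <- yaml::read_yaml(path)
    bad <- setdiff(names(over), c(names(cfg), "rarefy_depth"))
    if (length(bad) > 0L) stop("unknown config fields: ",
                               paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  dots <- list(...)
  if (length(dots) > 0L) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) > 0L) stop("unknown config fields: ",
                               paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  int_fields <- c("replicates", "n_final", "seed", "strain_seed",
                  "rarefy_seed", "max_error_reads", "error_grid_replicate",
                  "max_errors", "min_len")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  if (!is.null(cfg$rarefy_depth)) cfg$rarefy_depth <-
      as.integer(cfg$rarefy_depth)
  stopifnot(all(cfg$trim_grid %in% TRIM_GRID),
            cfg$eval_trim_level %in% TRIM_GRID,
            cfg$chimera_mode %in% c("balanced", "sensitive"),
            cfg$replicates >= 1L, cfg$n_final >= 1L)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' MD5 hash of a run configuration
#'
#' Hashes the YAML serialization of the config; stamped into every output
#' table header for provenance.
#'
#' @param config A `run_config`.
#' @return Hex MD5 string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

# write a TSV with provenance header comments
.write_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# config_hash: ", hash),
               paste0("# table: ", basename(path))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report or manifest TSV, skipping header comments
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

.log <- function(...) message("[mockamp] ", sprintf(...))

.method_code <- c(non_phasing = "NP", one_step_phasing = "P1",
                  two_step_phasing = "P2")

# the three study designs by name
.design_for <- function(community, strains) {
  switch(community,
    Bm1 = design_bm1(strains),
    Bm2 = design_bm2(strains),
    Bm3 = design_bm3(strains),
    stop("unknown community: ", community)
  )
}

#' Simulate the full library set of a run
#'
#' Generates the synthetic strain panel, the three community designs and
#' the external database, then one simulated library per (community x
#' method x replicate): paired FASTQ files plus a truth sidecar TSV.
#' Deterministic under `config$seed`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (one row per library with
#'   file paths and the per-library seed).
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  .log("simulate: config hash %s", hash)
  st0 <- synth_mock_strains(seed = config$strain_seed)
  st <- extract_v4_all(st0)
  st <- assign_gc_clusters(st, overrides = attr(st0, "cluster_truth"))
  contaminants <- synth_contaminants()
  db <- synth_external_db(st, contaminants = contaminants)
  mock_refs <- stats::setNames(st$v4_seq, st$strain_id)
  mock_refs <- mock_refs[!is.na(mock_refs)]
  write_fasta(mock_refs, file.path(out_dir, "mock_refs.fasta"))
  write_fasta(db, file.path(out_dir, "external_db.fasta"))
  write_run_config(config, file.path(out_dir, "config.yaml"))
  rows <- list()
  lib_index <- 0L
  for (community in config$communities) {
    design <- .design_for(community, st)
    write_design_tsv(design, file.path(out_dir,
                                       paste0("design_", community, ".tsv")))
    for (method in config$methods) {
      for (r in seq_len(config$replicates)) {
        lib_index <- lib_index + 1L
        lib_id <- sprintf("%s_%s_rep%02d", community,
                          .method_code[[method]], r)
        lib_seed <- derive_seed(config$seed, lib_index)
        spacer <- if (method == "non_phasing") 0L else (r - 1L) %% 8L
        p <- method_params(method, spacer_fwd = spacer,
                           contaminant_rate = config$contaminant_rate,
                           seed = lib_seed)
        pool <- simulate_pcr(design, p, n_final = config$n_final)
        set.seed(derive_seed(lib_seed, 3L))
        pool <- inject_contaminants(pool, contaminants,
                                    config$contaminant_rate)
        rd <- simulate_reads(pool, p, lib_id)
        r1 <- file.path(out_dir, paste0(lib_id, "_R1.fastq"))
        r2 <- file.path(out_dir, paste0(lib_id, "_R2.fastq"))
        tr <- file.path(out_dir, paste0(lib_id, "_truth.tsv"))
        write_fastq(rd$fwd, r1)
        write_fastq(rd$rev, r2)
        write_truth_tsv(rd$truth, tr)
        .log("simulate: %s (%d read pairs)", lib_id, length(rd$fwd))
        rows[[lib_index]] <- data.frame(
          library_id = lib_id, community = community, method = method,
          replicate = r, spacer_fwd = spacer, seed = lib_seed,
          fastq_r1 = basename(r1), fastq_r2 = basename(r2),
          truth = basename(tr), stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  .write_tsv(manifest, file.path(out_dir, "manifest.tsv"), hash)
  invisible(manifest)
}

# truth origin -> coarse truth class used in the confusion report
.truth_class <- function(origin) {
  c(strain = "true_strain", chimera = "chimera",
    contaminant = "contaminant")[origin]
}

#' Evaluate a simulated (or compatible) run
#'
#' Runs the evaluation pipeline on every library of a [run_simulate()]
#' bundle: trimming and merging, optional rarefaction, dual-reference
#' chimera accounting, the error-rate grid, pooled OTU clustering with
#' unique-OTU flags and artifact classification, and observed-vs-expected
#' bias statistics. Writes the report bundle as TSVs (each stamped with the
#' config hash): `chimera_rates.tsv`, `error_rates.tsv`,
#' `cluster_bias.tsv`, `pearson.tsv`, `unique_otus.tsv`,
#' `otu_classes.tsv`, and — when truth sidecars are present —
#' `confusion.tsv`.
#'
#' @param reads_dir Directory produced by [run_simulate()] (must contain
#'   `manifest.tsv`, `mock_refs.fasta`, `external_db.fasta` and the design
#'   TSVs).
#' @param out_dir Output directory for the report bundle.
#' @param config A [run_config()]; defaults to the one stored in
#'   `reads_dir`.
#' @return Invisibly, a list of the report data.frames.
#' @export
run_evaluate <- function(reads_dir, out_dir, config = NULL) {
  for (f in c("manifest.tsv", "mock_refs.fasta", "external_db.fasta")) {
    if (!file.exists(file.path(reads_dir, f))) {
      stop("missing input: ", file.path(reads_dir, f))
    }
  }
  if (is.null(config)) config <- run_config(file.path(reads_dir,
                                                      "config.yaml"))
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  .log("evaluate: config hash %s", hash)
  manifest <- read_report_tsv(file.path(reads_dir, "manifest.tsv"))
  mock_refs <- read_fasta(file.path(reads_dir, "mock_refs.fasta"))
  db <- read_fasta(file.path(reads_dir, "external_db.fasta"))
  chim_rows <- list()
  err_rows <- list()
  merged_by_lib <- list()
  truth_by_lib <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    fwd <- read_fastq(file.path(reads_dir, m$fastq_r1))
    rev <- read_fastq(file.path(reads_dir, m$fastq_r2))
    qc <- qc_library(fwd, rev, config$eval_trim_level,
                     min_len = config$min_len)
    merged <- qc$merged
    if (!is.null(config$rarefy_depth) && length(merged) > 0L) {
      keep <- rarefy(seq_len(length(merged)), depth = config$rarefy_depth,
                     seed = derive_seed(config$rarefy_seed, i),
                     library_id = m$library_id)
      merged <- merged[sort(keep)]
    }
    merged_by_lib[[m$library_id]] <- merged
    tr_path <- file.path(reads_dir, m$truth)
    if (file.exists(tr_path)) {
      truth_by_lib[[m$library_id]] <- read_truth_tsv(tr_path)
    }
    if (length(merged) > 0L) {
      acc <- chimera_accounting(merged$seq, mock_refs, db,
                                mode = config$chimera_mode,
                                read_ids = merged$id)
      chim_rows[[i]] <- data.frame(
        library_id = m$library_id, community = m$community,
        method = m$method, replicate = m$replicate,
        n_reads = acc$n_reads, rate_true = acc$rate_true,
        rate_detected = acc$rate_detected,
        rate_undetected = acc$rate_undetected,
        gc_chimeric = acc$gc_summary[["chimeric"]],
        gc_non_chimeric = acc$gc_summary[["non_chimeric"]],
        stringsAsFactors = FALSE
      )
      detected_ids <- names(acc$detected_chimera)[acc$detected_chimera]
    } else {
      detected_ids <- character(0)
      .log("evaluate: %s has no merged reads", m$library_id)
    }
    if (m$replicate == config$error_grid_replicate && length(fwd) > 0L) {
      eg <- error_grid(fwd, rev, mock_refs, trim_grid = config$trim_grid,
                       chimera_ids = detected_ids,
                       min_len = config$min_len,
                       max_reads = config$max_error_reads)
      eg <- cbind(data.frame(library_id = m$library_id,
                             community = m$community, method = m$method,
                             stringsAsFactors = FALSE), eg)
      err_rows[[i]] <- eg
    }
    .log("evaluate: %s done (%d merged reads)", m$library_id,
         length(merged))
  }
  chimera_rates <- do.call(rbind, chim_rows)
  error_rates <- do.call(rbind, err_rows)
  # community-level OTU and bias analysis on pooled merged reads
  bias_rows <- list()
  pearson_rows <- list()
  unique_rows <- list()
  class_rows <- list()
  confusion <- NULL
  for (community in unique(manifest$community)) {
    libs <- manifest$library_id[manifest$community == community]
    seqs <- unlist(lapply(libs, function(l) merged_by_lib[[l]]$seq),
                   use.names = FALSE)
    ids <- unlist(lapply(libs, function(l) merged_by_lib[[l]]$id),
                  use.names = FALSE)
    lib_of <- rep(libs, vapply(libs, function(l) {
      length(merged_by_lib[[l]])
    }, 1L))
    if (length(seqs) == 0L) {
      .log("evaluate: community %s has no reads, skipping", community)
      next
    }
    ot <- build_otu_table(seqs, lib_of,
                          identity_threshold = config$identity_threshold,
                          max_errors = config$max_errors)
    ot <- flag_unique_otus(ot)
    ot <- classify_artifacts(ot, mock_refs, db, mode = config$chimera_mode)
    us <- unique_otu_summary(ot)
    unique_rows[[community]] <- data.frame(
      community = community, as.data.frame(us), stringsAsFactors = FALSE
    )
    cls <- sub(":.*", "", ot$classification)
    class_rows[[community]] <- data.frame(
      community = community, otu_id = names(ot$classification),
      class = unname(ot$classification), flag = unname(ot$flags),
      total_count = rowSums(ot$counts), stringsAsFactors = FALSE
    )
    design_path <- file.path(reads_dir, paste0("design_", community,
                                               ".tsv"))
    if (file.exists(design_path) && length(libs) >= 2L) {
      dtab <- utils::read.delim(design_path, stringsAsFactors = FALSE)
      design <- structure(list(
        strains = dtab,
        expected_abundance = stats::setNames(dtab$expected_percent,
                                             dtab$strain_id),
        design_name = community,
        mode = if (length(unique(dtab$expected_percent)) == 1L) "even"
               else "tiered"
      ), class = "mock_design")
      abund <- observed_abundances(ot, design)
      rep_bias <- bias_report(abund, design)
      bias_rows[[community]] <- cbind(
        data.frame(community = community, stringsAsFactors = FALSE),
        rep_bias$per_cluster
      )
      pearson_rows[[community]] <- data.frame(
        community = community, library_id = names(rep_bias$pearson),
        pearson_r = unname(rep_bias$pearson), stringsAsFactors = FALSE
      )
    }
    # truth-vs-call confusion, per read, when sidecars are present
    if (length(truth_by_lib) > 0L) {
      truth <- do.call(rbind, truth_by_lib[libs])
      t_cls <- .truth_class(truth$origin[match(ids, truth$read_id)])
      call_cls <- cls[match(ot$read_otu, names(ot$classification))]
      keep <- !is.na(t_cls)
      tab <- as.data.frame(table(truth = t_cls[keep], call = call_cls[keep]))
      tab <- cbind(data.frame(community = community,
                              stringsAsFactors = FALSE), tab)
      confusion <- rbind(confusion, tab)
    }
  }
  reports <- list(
    chimera_rates = chimera_rates, error_rates = error_rates,
    cluster_bias = do.call(rbind, bias_rows),
    pearson = do.call(rbind, pearson_rows),
    unique_otus = do.call(rbind, unique_rows),
    otu_classes = do.call(rbind, class_rows),
    confusion = confusion
  )
  for (nm in names(reports)) {
    if (!is.null(reports[[nm]])) {
      .write_tsv(reports[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                 hash)
    }
  }
  .log("evaluate: report bundle written to %s", out_dir)
  invisible(reports)
}

#' Summarise a report bundle
#'
#' Reads the TSVs written by [run_evaluate()] and prints a short plain-text
#' summary (chimera rates by method, error-rate range, Pearson summary).
#'
#' @param bundle_dir Directory containing the report bundle.
#' @return Invisibly, the list of report data.frames.
#' @export
run_report <- function(bundle_dir) {
  paths <- list.files(bundle_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(paths) == 0L) stop("no report TSVs found in ", bundle_dir)
  reports <- lapply(paths, read_report_tsv)
  names(reports) <- sub("\\.tsv$", "", basename(paths))
  if (!is.null(reports$chimera_rates)) {
    agg <- stats::aggregate(rate_true ~ method, reports$chimera_rates, mean)
    cat("Mean truth chimera rate by method:\n")
    print(agg, row.names = FALSE)
  }
  if (!is.null(reports$error_rates)) {
    r <- range(reports$error_rates$rate_sub, na.rm = TRUE)
    cat(sprintf("Substitution error rate range: %.3f%% - %.3f%%\n",
                r[1], r[2]))
  }
  if (!is.null(reports$pearson)) {
    cat(sprintf("Observed-vs-expected Pearson r: mean %.3f over %d libraries\n",
                mean(reports$pearson$pearson_r, na.rm = TRUE),
                nrow(reports$pearson)))
  }
  invisible(reports)
}
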