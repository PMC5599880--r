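# End-to-end orchestration: simulate -> qc -> classify -> tabulate ->
# consensus -> quantify, driven by one flat config with a master seed from
# which every stage derives its own sub-seed.

#' Build a pipeline run configuration
#'
#' All values have working defaults; the study preset
#' ([study_config]) reproduces the desk-scale mixture experiment.
#'
#' @param seed master integer seed; every stochastic stage derives a
#'   sub-seed from it.
#' @param out_dir output directory.
#' @param n_taxa taxa per end member.
#' @param shared_taxa number of taxa shared between the end members.
#' @param divergence reference-set divergence from the common ancestor.
#' @param lognormal_sigma abundance skew of each end-member community.
#' @param fractions,replicates mixture design (see [mixture_design]).
#' @param n_reads reads per sample.
#' @param sub_rate,ins_rate,del_rate error model (see [error_model]).
#' @param junk_fraction off-target read fraction.
#' @param len_16s,len_its,len_23s operon architecture (see [operon_model]).
#' @param min_len,max_len,min_sites QC thresholds (see [qc_filter]).
#' @param min_identity,min_span classifier floor (see [classify_reads]).
#' @param consensus_min_reads reads required to reconstruct an OTU.
#' @param consensus_max_otus reconstruct at most this many OTUs (0 = skip).
#' @param top_k OTUs per end member in the mixture regression.
#' @param run_sensitivity run the error-injection sensitivity analysis.
#' @return a `run_config` (named list, serializable with
#'   [write_run_config]).
#' @export
run_config <- function(seed = 42, out_dir = tempfile("ribopore_run_"),
                       n_taxa = 50, shared_taxa = 0, divergence = 0.15,
                       lognormal_sigma = 2,
                       fractions = c(0, 0.1, 0.2, 0.5, 0.75, 1),
                       replicates = 4, n_reads = 500,
                       sub_rate = 0.06, ins_rate = 0.03, del_rate = 0.03,
                       junk_fraction = 0.05,
                       len_16s = 1500, len_its = 300, len_23s = 2400,
                       min_len = 4000, max_len = 5000, min_sites = 2,
                       min_identity = 70, min_span = 500,
                       consensus_min_reads = 30, consensus_max_otus = 3,
                       top_k = 4, run_sensitivity = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = c("run_config", "list"))
}

#' Desk-scale preset mirroring the mixture experiment
#'
#' Two 50-taxon end members mixed at 0/10/20/50/75/100 percent in
#' quadruplicate, 500 reads per sample at 12 percent error, full 4.2 kb
#' operons.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param ... overrides passed to [run_config].
#' @return a `run_config`.
#' @export
study_config <- function(seed = 42, out_dir = tempfile("ribopore_run_"),
                         ...) {
  run_config(seed = seed, out_dir = out_dir, ...)
}

# order-insensitive content hash of the config (31-ary string hash)
config_hash <- function(cfg) {
  keys <- sort(names(cfg)[!names(cfg) %in% "out_dir"])
  txt <- paste(keys, vapply(cfg[keys], function(v)
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ","), ""),
    sep = "=", collapse = ";")
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_stamped <- function(writer, obj, path, cfg) {
  writer(obj, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order, writes all outputs under
#' `config$out_dir` (each TSV carries a comment header with the config hash
#' and master seed), and returns a manifest with per-stage status, seeds
#' and wall times. Re-running with an identical config reproduces identical
#' outputs. OTUs eligible for consensus but below
#' `consensus_min_reads` are skipped with a logged warning.
#'
#' @param config a [run_config].
#' @return a `pipeline_manifest` list: config, hash, stage table, and the
#'   in-memory stage results (`results`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_all <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stamp <- paste0("# ribopore config=", hash, " seed=", config$seed)
  stages <- list()
  mark <- function(name, t0, status = "ok", seed = NA) {
    stages[[name]] <<- data.frame(
      stage = name, status = status, seed = seed,
      wall_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
      stringsAsFactors = FALSE)
  }
  res <- list()
  write_run_config(unclass(config)[!vapply(config, is.null, TRUE)],
                   file.path(config$out_dir, "run.cfg"))

  ## 1. reference set + end-member communities
  t0 <- Sys.time()
  seed_ref <- derive_seed(config$seed, "refset")
  model <- operon_model(len_16s = config$len_16s, len_its = config$len_its,
                        len_23s = config$len_23s)
  n_total <- 2 * config$n_taxa - config$shared_taxa
  ref <- generate_reference_set(n_total, config$divergence, model, seed_ref)
  pool_a <- ref$taxon_ids[seq_len(config$n_taxa)]
  pool_b <- ref$taxon_ids[(config$n_taxa - config$shared_taxa + 1):n_total]
  prof_a <- sample_community(pool_a, config$lognormal_sigma,
                             derive_seed(config$seed, "community", "A"))
  prof_b <- sample_community(pool_b, config$lognormal_sigma,
                             derive_seed(config$seed, "community", "B"))
  write_fasta(ref$operons, file.path(config$out_dir, "reference_operons.fasta"))
  write_fasta(ref$sixteen_s, file.path(config$out_dir, "reference_16s.fasta"))
  write_fasta(ref$panel, file.path(config$out_dir, "primer_panel.fasta"))
  res$ref <- ref; res$profiles <- list(A = prof_a, B = prof_b)
  mark("reference", t0, seed = seed_ref)

  ## 2. mixtures + reads
  t0 <- Sys.time()
  design <- mixture_design(config$fractions, config$replicates)
  em <- error_model(config$sub_rate, config$ins_rate, config$del_rate)
  sim <- list()
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]
    prof <- mix_profiles(prof_a, prof_b, design$fraction_a[i])
    sim[[sid]] <- simulate_reads(prof, ref, config$n_reads, em,
                                 derive_seed(config$seed, "reads", sid),
                                 config$junk_fraction, read_prefix = sid)
  }
  truth <- do.call(rbind, lapply(sim, `[[`, "truth"))
  utils::write.table(truth, file.path(config$out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$design <- design; res$sim <- sim
  mark("simulate", t0, seed = config$seed)

  ## 3. QC + 16S extraction
  t0 <- Sys.time()
  qc <- lapply(sim, function(s)
    qc_reads(s$reads, ref$panel, min_len = config$min_len,
             max_len = config$max_len, min_sites = config$min_sites))
  qc_report <- do.call(rbind, lapply(qc, `[[`, "report"))
  utils::write.table(qc_report, file.path(config$out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$qc <- qc
  mark("qc", t0)

  ## 4. classification
  t0 <- Sys.time()
  index <- build_index(ref)
  assignments <- list()
  for (sid in names(qc)) {
    ex <- qc[[sid]]$extracted_16s
    if (is.null(ex)) {
      rp_log("sample ", sid, ": no extracted 16S sequences", force = TRUE)
      next
    }
    assignments[[sid]] <- classify_reads(ex, index,
                                         min_identity = config$min_identity,
                                         min_span = config$min_span,
                                         sample_id = sid)
  }
  asn <- do.call(rbind, assignments)
  counts <- tabulate_assignments(asn)
  freqs <- normalize_otu_table(counts)
  write_otu_table(counts, file.path(config$out_dir, "otu_counts.tsv"))
  utils::write.table(
    data.frame(otu_id = rownames(freqs), freqs, check.names = FALSE),
    file.path(config$out_dir, "otu_freqs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  res$index <- index; res$assignments <- asn
  res$counts <- counts; res$freqs <- freqs
  mark("classify", t0)

  ## 5. consensus reconstruction (pooled reads per OTU)
  t0 <- Sys.time()
  res$consensus <- list()
  if (config$consensus_max_otus > 0) {
    kept_all <- do.call(rbind, lapply(qc, `[[`, "kept"))
    class(kept_all) <- c("seq_records", "data.frame")
    per_otu <- sort(table(asn$otu_id[asn$classified]), decreasing = TRUE)
    targets <- names(per_otu)[seq_len(min(config$consensus_max_otus,
                                          length(per_otu)))]
    cons_records <- list()
    for (otu in targets) {
      if (per_otu[[otu]] < config$consensus_min_reads) {
        rp_log("consensus: skipping ", otu, " (", per_otu[[otu]],
               " reads < ", config$consensus_min_reads, ")", force = TRUE)
        next
      }
      sel <- select_otu_reads(asn, kept_all, otu, config$consensus_min_reads)
      sched <- round(config$consensus_min_reads * c(1, 2, 3) / 3)
      it <- iterative_consensus(sel, schedule = sched, otu_id = otu)
      cons_records[[otu]] <- it
    }
    if (length(cons_records)) {
      fasta <- seq_records(
        names(cons_records),
        vapply(cons_records, function(x) x$final$sequence, ""),
        desc = vapply(cons_records, function(x)
          sprintf("stage=%s n_reads=%d mean_cov=%.1f disagreements=%d",
                  x$final$stage, x$final$n_reads,
                  mean(x$final$per_column_coverage),
                  x$final$disagreements), ""))
      write_fasta(fasta, file.path(config$out_dir, "consensus.fasta"))
    }
    res$consensus <- cons_records
  }
  mark("consensus", t0)

  ## 6. quantitation
  t0 <- Sys.time()
  reg <- top_k_response(freqs, design, k = config$top_k, counts = counts)
  utils::write.table(reg, file.path(config$out_dir, "mixture_regression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$regression <- reg
  if (isTRUE(config$run_sensitivity)) {
    sens <- sensitivity_run(ref, seed = derive_seed(config$seed, "sens"),
                            index = index)
    utils::write.table(sens$table,
                       file.path(config$out_dir, "sensitivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$sensitivity <- sens
  }
  mark("quantify", t0)

  manifest <- structure(list(
    config = config, hash = hash,
    stages = do.call(rbind, stages),
    wall_s = round(as.numeric(difftime(Sys.time(), t_all, units = "secs")), 2),
    out_dir = config$out_dir, results = res), class = "pipeline_manifest")
  man_txt <- c(stamp,
               apply(manifest$stages, 1, paste, collapse = "\t"))
  writeLines(man_txt, file.path(config$out_dir, "manifest.tsv"))
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("ribopore pipeline run [config ", x$hash, ", seed ",
      x$config$seed, "]: ", x$wall_s, " s\n", sep = "")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
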