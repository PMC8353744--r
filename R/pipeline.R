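#' Pipeline configuration
#'
#' Every threshold of every stage in one place; all values are
#' overridable here or via a YAML file ([read_pipeline_config()]) and
#' are echoed verbatim into the run log.
#'
#' @param min_seqs minimum transcript count per sample; "less than" is
#'   strict, so a sample with exactly `min_seqs` transcripts is kept.
#' @param cc_threshold cross-contamination percentage at or above which
#'   two same-genus samples are considered closely related and pooled.
#' @param edge_rule how the two directed values combine ("max", "min",
#'   "mean"); see [build_pools()].
#' @param derep_identity dereplication identity threshold (percent).
#' @param derep_word_size word size of the dereplication prefilter.
#' @param k canonical k-mer size for read attribution.
#' @param min_share minimum shared k-mers for read attribution.
#' @param R expression ratio declaring a cross-contaminant.
#' @param min_expr TPM-like expression floor.
#' @param fence_k Tukey fence multiplier.
#' @param min_group minimum units per phylum for outlier fencing.
#' @param outlier_method "tukey" or "mad".
#' @param frag_frac completeness fraction, see [assess_completeness()].
#' @param min_score,min_identity marker-hit retention thresholds.
#' @param seed RNG seed recorded with the run (the pipeline itself is
#'   deterministic; the seed is carried for provenance).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_seqs = 5000L, cc_threshold = 10,
                            edge_rule = "max", derep_identity = 95,
                            derep_word_size = 8L, k = 21L, min_share = 2L,
                            R = 2, min_expr = 0.5, fence_k = 1.5,
                            min_group = 4L, outlier_method = "tukey",
                            frag_frac = 0.7, min_score = 50,
                            min_identity = 30, seed = 1L) {
  structure(list(min_seqs = as.integer(min_seqs),
                 cc_threshold = cc_threshold, edge_rule = edge_rule,
                 derep_identity = derep_identity,
                 derep_word_size = as.integer(derep_word_size),
                 k = as.integer(k), min_share = as.integer(min_share),
                 R = R, min_expr = min_expr, fence_k = fence_k,
                 min_group = as.integer(min_group),
                 outlier_method = outlier_method, frag_frac = frag_frac,
                 min_score = min_score, min_identity = min_identity,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys missing from the file keep their [pipeline_config()] defaults;
#' unknown keys are a configuration error.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Size / readability / taxonomy filter
#'
#' Discards samples with fewer than `min_seqs` transcripts
#' (`too_few_seqs`; strictly fewer — a sample at exactly the threshold
#' is kept), unreadable FASTA/FASTQ files (`corrupt_file`), and samples
#' with an empty phylum or genus (`unknown_taxon`). Failure modes never
#' raise: they become discard records.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param min_seqs minimum transcript count.
#' @return a list: `kept` (list of loaded `derepool_sample`s),
#'   `kept_manifest`, `discarded` (data.frame: unit_id, stage, reason,
#'   member_samples).
#' @export
filter_min_seqs <- function(manifest, min_seqs = 5000L) {
  kept <- list()
  kept_rows <- integer(0)
  disc <- list()
  add_disc <- function(id, reason) {
    disc[[length(disc) + 1L]] <<- data.frame(
      unit_id = id, stage = "filter", reason = reason,
      member_samples = id, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    if (!nzchar(row$phylum) || !nzchar(row$genus)) {
      add_disc(row$sample_id, "unknown_taxon")
      next
    }
    s <- tryCatch(load_sample(row), derepool_error = function(e) NULL,
                  error = function(e) NULL)
    if (is.null(s)) {
      add_disc(row$sample_id, "corrupt_file")
      next
    }
    if (length(s$transcripts) < min_seqs) {
      add_disc(row$sample_id, "too_few_seqs")
      next
    }
    kept[[length(kept) + 1L]] <- s
    kept_rows <- c(kept_rows, i)
  }
  discarded <- if (length(disc) > 0L) do.call(rbind, disc) else
    data.frame(unit_id = character(), stage = character(),
               reason = character(), member_samples = character(),
               stringsAsFactors = FALSE)
  list(kept = kept, kept_manifest = manifest[kept_rows, , drop = FALSE],
       discarded = discarded)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full consolidation pipeline
#'
#' Stages, in order: minimum-size filter; ribosomal-marker screen;
#' phylum-wise outlier discard (pass 1); cross-contamination matrix;
#' genus/relatedness pooling; pool merging; dereplication;
#' cross-contamination and marker screen on the consolidated units;
#' phylum-wise outlier discard (pass 2, union of both detectors);
#' marker-recovery completeness. Every stage writes its TSV/CSV report
#' under `out_dir`; the final transcriptomes, the discard log and a run
#' log (plain text + JSON, with every threshold echoed) complete the
#' output. Conservation is asserted: every input sample ends up in
#' exactly one output transcriptome or one discard entry.
#'
#' @param manifest_path path to the sample manifest TSV.
#' @param marker_db_path path to the marker FASTA.
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @param threads worker processes for per-sample stages (attribution,
#'   screening). Results are bit-identical to a serial run.
#' @return invisibly, a list with the main in-memory results:
#'   `final_units`, `discard_log`, `pool_plan`, `counts` (per-stage
#'   accounting), `out_dir`.
#' @export
run_pipeline <- function(manifest_path, marker_db_path, out_dir,
                         config = pipeline_config(), threads = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "pools"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "final"), showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
  }
  apply_fun <- function(x, f) {
    if (threads > 1L) parallel::mclapply(x, f, mc.cores = threads)
    else lapply(x, f)
  }

  manifest <- read_manifest(manifest_path)
  marker_db <- read_marker_db(marker_db_path)
  n_input <- nrow(manifest)
  note("input samples: %d", n_input)

  # ---- stage 1: filter
  flt <- filter_min_seqs(manifest, config$min_seqs)
  discard_log <- flt$discarded
  samples <- flt$kept
  note("filter: kept %d, discarded %d", length(samples), nrow(discard_log))

  # ---- stage 2: marker screen (pass 1)
  hits1 <- apply_fun(samples, function(s)
    screen_sample(s, marker_db, min_score = config$min_score,
                  min_identity = config$min_identity))
  est1 <- do.call(rbind, lapply(seq_along(samples), function(i) {
    e <- estimate_contamination(hits1[[i]], samples[[i]]$taxonomy)
    e$sample_id <- samples[[i]]$sample_id
    e$phylum <- samples[[i]]$taxonomy$phylum
    e
  }))
  write_tsv(do.call(rbind, hits1), file.path(out_dir, "marker_hits_pass1.tsv"))
  utils::write.csv(est1, file.path(out_dir, "contamination_pass1.csv"),
                   row.names = FALSE)

  # ---- stage 3: phylum outlier discard (pass 1)
  out1 <- detect_outliers(
    data.frame(unit_id = est1$sample_id, phylum = est1$phylum,
               contamination_pct = est1$contamination_pct,
               stringsAsFactors = FALSE),
    fence_k = config$fence_k, min_group = config$min_group,
    method = config$outlier_method)
  utils::write.csv(out1, file.path(out_dir, "outliers_pass1.csv"),
                   row.names = FALSE)
  flagged1 <- out1$unit_id[out1$flagged]
  if (length(flagged1) > 0L) {
    discard_log <- rbind(discard_log, data.frame(
      unit_id = flagged1, stage = "marker_screen_pass1",
      reason = "marker_outlier", member_samples = flagged1,
      stringsAsFactors = FALSE))
  }
  samples <- samples[!vapply(samples, function(s) s$sample_id, "") %in%
                       flagged1]
  note("outlier pass 1: discarded %d, %d samples remain",
       length(flagged1), length(samples))

  # ---- stage 4: cross-contamination matrix
  cc <- cross_contamination(samples, k = config$k,
                            min_share = config$min_share, R = config$R,
                            min_expr = config$min_expr, threads = threads)
  utils::write.csv(as.data.frame(cc$matrix),
                   file.path(out_dir, "crosscontam_matrix.csv"))
  write_tsv(cc$verdicts, file.path(out_dir, "crosscontam_verdicts.tsv"))

  # ---- stage 5: pooling
  taxa <- do.call(rbind, lapply(samples, function(s) data.frame(
    sample_id = s$sample_id, phylum = s$taxonomy$phylum,
    genus = s$taxonomy$genus, stringsAsFactors = FALSE)))
  plan <- build_pools(taxa, cc$matrix, threshold_pct = config$cc_threshold,
                      rule = config$edge_rule)
  write_tsv(plan$pools, file.path(out_dir, "pool_plan.tsv"))
  note("pooling: %d pools (%d combined)", nrow(plan$pools),
       sum(plan$pools$kind == "combined"))

  # ---- stages 6-7: merge + dereplicate per pool
  sample_by_id <- stats::setNames(samples,
                                  vapply(samples, function(s) s$sample_id, ""))
  units <- apply_fun(seq_len(nrow(plan$pools)), function(pi) {
    pool <- plan$pools[pi, ]
    members <- strsplit(pool$members, ";", fixed = TRUE)[[1L]]
    member_tr <- lapply(sample_by_id[members], function(s) s$transcripts)
    names(member_tr) <- members
    merged <- merge_pool(pool$pool_id, member_tr)
    derep <- dereplicate(merged, config$derep_identity,
                         config$derep_word_size)
    reps <- merged[derep$representatives]
    list(pool_id = pool$pool_id, members = members, merged_n = length(merged),
         derep = derep, transcripts = reps)
  })
  for (u in units) {
    write_fasta(u$transcripts,
                file.path(out_dir, "pools", paste0(u$pool_id, ".fasta")))
    write_clusters(u$derep,
                   file.path(out_dir, "pools", paste0(u$pool_id, ".clstr.tsv")))
  }
  note("dereplication: %s",
       paste(vapply(units, function(u) sprintf("%s %d->%d", u$pool_id,
                                               u$merged_n,
                                               length(u$transcripts)), ""),
             collapse = ", "))

  # ---- stage 8: screens on consolidated units
  unit_phylum <- vapply(units, function(u) {
    ph <- unique(taxa$phylum[taxa$sample_id %in% u$members])
    ph[1L]
  }, "")
  unit_samples <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    reads <- unlist(lapply(u$members, function(m) {
      r <- as.character(sample_by_id[[m]]$reads)
      names(r) <- paste(m, names(r), sep = ".")
      r
    }))
    structure(list(sample_id = u$pool_id,
                   taxonomy = list(phylum = unit_phylum[i]),
                   transcripts = u$transcripts,
                   reads = Biostrings::DNAStringSet(reads)),
              class = "derepool_sample")
  })

  hits2 <- apply_fun(unit_samples, function(s)
    screen_sample(s, marker_db, min_score = config$min_score,
                  min_identity = config$min_identity))
  est2 <- do.call(rbind, lapply(seq_along(unit_samples), function(i) {
    e <- estimate_contamination(hits2[[i]], unit_phylum[i])
    e$sample_id <- unit_samples[[i]]$sample_id
    e$phylum <- unit_phylum[i]
    e
  }))
  utils::write.csv(est2, file.path(out_dir, "contamination_pass2.csv"),
                   row.names = FALSE)

  cc2 <- if (length(unit_samples) > 1L) {
    cross_contamination(unit_samples, k = config$k,
                        min_share = config$min_share, R = config$R,
                        min_expr = config$min_expr, threads = threads)
  } else NULL
  cc_score <- vapply(seq_along(unit_samples), function(i) {
    if (is.null(cc2)) return(0)
    v <- cc2$verdicts[cc2$verdicts$owner_sample ==
                        unit_samples[[i]]$sample_id, ]
    100 * sum(v$category == "crosscontam") / nrow(v)
  }, 0)
  if (!is.null(cc2)) {
    utils::write.csv(as.data.frame(cc2$matrix),
                     file.path(out_dir, "crosscontam_matrix_pass2.csv"))
  }

  # ---- stage 9: phylum outlier discard (pass 2, union of detectors)
  out2m <- detect_outliers(
    data.frame(unit_id = est2$sample_id, phylum = est2$phylum,
               contamination_pct = est2$contamination_pct,
               stringsAsFactors = FALSE),
    fence_k = config$fence_k, min_group = config$min_group,
    method = config$outlier_method)
  out2c <- detect_outliers(
    data.frame(unit_id = est2$sample_id, phylum = est2$phylum,
               crosscontam_pct = cc_score, stringsAsFactors = FALSE),
    fence_k = config$fence_k, min_group = config$min_group,
    metric = "crosscontam_pct", method = config$outlier_method)
  utils::write.csv(rbind(out2m, out2c),
                   file.path(out_dir, "outliers_pass2.csv"),
                   row.names = FALSE)
  flag_cc <- out2c$unit_id[out2c$flagged]
  flag_mk <- setdiff(out2m$unit_id[out2m$flagged], flag_cc)
  drop_units <- c(flag_cc, flag_mk)
  if (length(drop_units) > 0L) {
    members_of <- function(uid) {
      u <- units[[which(vapply(units, function(x) x$pool_id, "") == uid)]]
      paste(u$members, collapse = ";")
    }
    discard_log <- rbind(discard_log, data.frame(
      unit_id = drop_units,
      stage = "consolidated_screen",
      reason = c(rep("crosscontam_outlier", length(flag_cc)),
                 rep("marker_outlier", length(flag_mk))),
      member_samples = vapply(drop_units, members_of, ""),
      stringsAsFactors = FALSE))
  }
  keep_units <- vapply(units, function(u) !(u$pool_id %in% drop_units),
                       TRUE)
  final_units <- units[keep_units]
  note("outlier pass 2: discarded %d unit(s), %d remain",
       length(drop_units), length(final_units))

  # ---- stage 10: completeness + final output
  compl <- if (length(final_units) > 0L) {
    do.call(rbind, lapply(final_units, function(u)
      assess_completeness(u$transcripts, marker_db, unit_id = u$pool_id,
                          frag_frac = config$frag_frac,
                          min_score = config$min_score,
                          min_identity = config$min_identity)))
  } else {
    data.frame(unit_id = character(), n_markers = integer(),
               n_complete = integer(), n_fragmented = integer(),
               n_missing = integer(), pct_complete = numeric())
  }
  utils::write.csv(compl, file.path(out_dir, "completeness.csv"),
                   row.names = FALSE)
  for (u in final_units) {
    write_fasta(u$transcripts,
                file.path(out_dir, "final", paste0(u$pool_id, ".fasta")))
  }
  rownames(discard_log) <- NULL
  write_tsv(discard_log, file.path(out_dir, "discard_log.tsv"))

  # ---- conservation check
  final_members <- unlist(lapply(final_units, function(u) u$members))
  discarded_members <- unlist(strsplit(discard_log$member_samples, ";",
                                       fixed = TRUE))
  accounted <- c(final_members, discarded_members)
  if (length(accounted) != n_input ||
      anyDuplicated(accounted) ||
      !setequal(accounted, manifest$sample_id)) {
    stop(sprintf("internal error: conservation violated (inputs %d, accounted %d)",
                 n_input, length(accounted)))
  }
  note("conservation: %d inputs = %d in final units + %d discarded",
       n_input, length(final_members), length(discarded_members))

  counts <- list(input = n_input, after_filter = length(flt$kept),
                 after_pass1 = length(samples), pools = nrow(plan$pools),
                 after_pass2 = length(final_units),
                 discarded = nrow(discard_log))
  # the log echoes configuration and accounting only; worker count is an
  # execution detail and must not break serial/parallel bit-identity
  run_log <- list(config = unclass(config), counts = counts)
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(final_units = final_units, discard_log = discard_log,
                 pool_plan = plan, counts = counts, out_dir = out_dir))
}
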