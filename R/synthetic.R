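AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification for a synthetic multi-sample transcriptome collection
#'
#' The generator plants every kind of structure the pipeline is supposed
#' to detect — cross-contaminated transcripts with donor-side read
#' depth, foreign-phylum marker copies, near-duplicate sequences — and
#' records each planted item in truth tables, so every stage can be
#' scored against ground truth. Output is fully deterministic under a
#' fixed seed.
#'
#' @param n_phyla number of phyla.
#' @param genera_per_phylum genera per phylum.
#' @param samples_per_genus samples per genus.
#' @param transcripts_per_sample transcripts per sample (total, including
#'   planted ones).
#' @param transcript_len length-2 vector: transcript length range (bases).
#' @param reads_per_sample reads simulated per sample.
#' @param read_len read length (bases).
#' @param n_marker_families number of ribosomal-marker families.
#' @param marker_len length-2 range of marker lengths (amino acids).
#' @param subst_rate per-site substitution rate separating phylum marker
#'   references from the family root.
#' @param marker_max_cross_score marker families are redrawn until no
#'   six-frame translation of any reverse-translated reference reaches
#'   this local-alignment score against another family, so a marker
#'   transcript can only ever hit its own family. When a dataset carries
#'   marker content (`marker_copies > 0`), background and near-duplicate
#'   transcripts are held to the same ceiling, so planted markers are
#'   the only transcripts that can produce retained marker hits.
#' @param marker_copies marker-derived transcripts per sample.
#' @param foreign_marker_fraction fraction of each sample's marker
#'   transcripts copied from a foreign phylum's reference; scalar or a
#'   named vector keyed by sample_id.
#' @param duplicate_fraction fraction of transcripts planted as
#'   near-duplicates of background transcripts.
#' @param duplicate_identity nucleotide identity of planted duplicates.
#' @param cross_contam_plan data.frame (donor, recipient, fraction,
#'   depth_mult): fraction of the recipient's transcripts replaced by
#'   verbatim copies of donor transcripts, whose recipient-side read
#'   depth is divided by depth_mult (the donor keeps full depth).
#' @param read_error_rate uniform substitution error rate on reads
#'   (default 0: the pipeline's claims concern attribution and
#'   thresholds, not error models).
#' @param seed RNG seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_phyla = 2L, genera_per_phylum = 2L,
                           samples_per_genus = 3L,
                           transcripts_per_sample = 120L,
                           transcript_len = c(300L, 800L),
                           reads_per_sample = 4000L, read_len = 100L,
                           n_marker_families = 10L,
                           marker_len = c(120L, 250L), subst_rate = 0.3,
                           marker_max_cross_score = 50,
                           marker_copies = 10L,
                           foreign_marker_fraction = 0,
                           duplicate_fraction = 0,
                           duplicate_identity = 96,
                           cross_contam_plan = NULL,
                           read_error_rate = 0, seed = 1L) {
  spec <- list(n_phyla = as.integer(n_phyla),
               genera_per_phylum = as.integer(genera_per_phylum),
               samples_per_genus = as.integer(samples_per_genus),
               transcripts_per_sample = as.integer(transcripts_per_sample),
               transcript_len = as.integer(transcript_len),
               reads_per_sample = as.integer(reads_per_sample),
               read_len = as.integer(read_len),
               n_marker_families = as.integer(n_marker_families),
               marker_len = as.integer(marker_len),
               subst_rate = subst_rate,
               marker_max_cross_score = marker_max_cross_score,
               marker_copies = as.integer(marker_copies),
               foreign_marker_fraction = foreign_marker_fraction,
               duplicate_fraction = duplicate_fraction,
               duplicate_identity = duplicate_identity,
               cross_contam_plan = cross_contam_plan,
               read_error_rate = read_error_rate,
               seed = as.integer(seed))
  if (any(unlist(spec[c("foreign_marker_fraction", "duplicate_fraction",
                        "read_error_rate")]) < 0) ||
      any(unlist(spec[c("foreign_marker_fraction",
                        "duplicate_fraction")]) > 1)) {
    stop_config("fractions must lie in [0, 1]")
  }
  if (!is.null(cross_contam_plan)) {
    need <- c("donor", "recipient", "fraction", "depth_mult")
    if (!all(need %in% names(cross_contam_plan))) {
      stop_config("cross_contam_plan needs columns %s",
                  paste(need, collapse = ", "))
    }
    if (any(cross_contam_plan$fraction < 0 | cross_contam_plan$fraction > 1)) {
      stop_config("cross-contamination fractions must lie in [0, 1]")
    }
  }
  structure(spec, class = "synthetic_spec")
}

#' Sample taxonomy table implied by a synthetic spec
#' @param spec a `synthetic_spec`.
#' @return data.frame: sample_id, phylum, genus, species, strain.
#' @export
synthetic_taxa <- function(spec) {
  rows <- list()
  g_global <- 0L
  for (p in seq_len(spec$n_phyla)) {
    phylum <- sprintf("Phy%02d", p)
    for (g in seq_len(spec$genera_per_phylum)) {
      g_global <- g_global + 1L
      genus <- sprintf("Genus%02d", g_global)
      for (s in seq_len(spec$samples_per_genus)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_s%02d", genus, s),
          phylum = phylum, genus = genus,
          species = sprintf("%s sp%d", genus, s), strain = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Reverse-translate an amino-acid sequence deterministically
#'
#' Uses the alphabetically first codon of each amino acid under the
#' standard genetic code (no codon-usage model: downstream analysis
#' re-translates, so only determinism matters).
#'
#' @param aa amino-acid string.
#' @return nucleotide string of length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa) {
  if (is.null(the_cache$codon_of)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- sort(names(gc))
    map <- vapply(unique(gc), function(a) codons[gc[codons] == a][1L], "")
    names(map) <- unique(gc)
    the_cache$codon_of <- map
  }
  paste(the_cache$codon_of[strsplit(aa, "")[[1L]]], collapse = "")
}

random_dna <- function(lens) {
  total <- sum(lens)
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  grp <- rep(seq_along(lens), lens)
  vapply(split(bases, grp), paste, "", collapse = "")
}

random_aa <- function(len) paste(sample(AA20, len, replace = TRUE),
                                 collapse = "")

mutate_aa <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

mutate_dna <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1L]]
  pos <- sample.int(length(ch), n_sub)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a taxon-labelled marker reference database
#'
#' One random amino-acid root per marker family, mutated independently
#' for each phylum at `subst_rate`; headers carry
#' `markerID|phylum|genus|refID`. With rate 0, all phyla share identical
#' references per family.
#'
#' @param spec a `synthetic_spec`.
#' @return data.frame in the [read_marker_db()] layout.
#' @export
generate_marker_db <- function(spec) {
  if (spec$n_marker_families < 1L || spec$n_phyla < 1L) {
    stop_config("need at least one marker family and one phylum")
  }
  set.seed(spec$seed)
  taxa <- synthetic_taxa(spec)
  phyla <- unique(taxa$phylum)
  rows <- list()
  accepted_res <- character(0)
  for (f in seq_len(spec$n_marker_families)) {
    fam <- sprintf("RP%02d", f)
    for (attempt in seq_len(50L)) {
      len <- sample(seq(spec$marker_len[1L], spec$marker_len[2L]), 1L)
      root <- random_aa(len)
      fam_res <- vapply(phyla, function(ph) {
        if (spec$subst_rate > 0) mutate_aa(root, spec$subst_rate) else root
      }, "")
      if (markers_cross_score(fam_res, accepted_res) <
          spec$marker_max_cross_score) break
      if (attempt == 50L) {
        stop_config("could not draw %d mutually dissimilar marker families",
                    spec$n_marker_families)
      }
    }
    for (p in seq_along(phyla)) {
      ph <- phyla[p]
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = fam, phylum = ph,
        genus = taxa$genus[match(ph, taxa$phylum)],
        ref_id = sprintf("%s_%s", fam, ph),
        residues = fam_res[p], ref_length = nchar(fam_res[p]),
        stringsAsFactors = FALSE)
    }
    accepted_res <- c(accepted_res, fam_res)
  }
  do.call(rbind, rows)
}

# Highest local-alignment score of any six-frame translation of the
# candidate family's reverse-translated references against any accepted
# reference (and vice versa); 0 when nothing is accepted yet. This is
# what a marker transcript of one family could maximally score against
# another family's references during screening.
markers_cross_score <- function(fam_res, accepted_res) {
  if (length(accepted_res) == 0L) return(0)
  nt <- Biostrings::DNAStringSet(vapply(fam_res, reverse_translate, ""))
  fr <- six_frames_set(nt)$aa
  acc_nt <- Biostrings::DNAStringSet(vapply(accepted_res, reverse_translate, ""))
  acc_fr <- six_frames_set(acc_nt)$aa
  best <- 0
  for (ref in accepted_res) {
    best <- max(best, sw_score_batch_cpp(fr, ref, blosum62(), 11, 1))
  }
  for (res in fam_res) {
    best <- max(best, sw_score_batch_cpp(acc_fr, res, blosum62(), 11, 1))
  }
  best
}

# Max local-alignment score of any six-frame translation of each
# sequence against any marker reference.
max_marker_score <- function(seqs, db) {
  if (length(seqs) == 0L) return(numeric(0))
  fr <- six_frames_set(Biostrings::DNAStringSet(unname(seqs)))
  best <- numeric(length(seqs))
  for (r in seq_len(nrow(db))) {
    sc <- sw_score_batch_cpp(fr$aa, db$residues[r], blosum62(), 11, 1)
    agg <- tapply(sc, fr$transcript, max)
    best <- pmax(best, as.numeric(agg[as.character(seq_along(seqs))]))
  }
  best
}

# Redraw sequences (via `redraw(i)`) until none reaches the score
# ceiling against the marker db. Only offenders are re-screened.
enforce_marker_dissimilar <- function(seqs, db, ceiling, redraw, what) {
  bad <- which(max_marker_score(seqs, db) >= ceiling)
  for (i in bad) {
    ok <- FALSE
    for (attempt in seq_len(50L)) {
      seqs[i] <- redraw(i)
      if (max_marker_score(seqs[i], db)[1L] < ceiling) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop_config("could not draw marker-dissimilar %s transcripts",
                         what)
  }
  seqs
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Writes a manifest TSV, per-sample transcript FASTA and read FASTQ
#' files, the marker FASTA, and truth tables
#' (`planted_crosscontam.tsv`, `planted_foreign.tsv`,
#' `planted_duplicates.tsv`) under `dir`. Per sample, the transcripts
#' comprise reverse-translated own-phylum marker copies, random
#' background, near-duplicates of background transcripts, planted
#' foreign-phylum marker copies, and verbatim copies of donor
#' transcripts per `cross_contam_plan`. Reads are drawn uniformly over
#' the sample's transcripts except that planted cross-contaminant
#' transcripts are covered at `1/depth_mult` of the uniform rate (the
#' donor keeps full depth on its own originals).
#'
#' @param spec a `synthetic_spec`.
#' @param dir output directory (created if absent).
#' @return invisibly, a list: `manifest` (data.frame), `marker_db`,
#'   `truth` (list of data.frames), `dir`.
#' @export
generate_dataset <- function(spec, dir) {
  db <- generate_marker_db(spec)
  set.seed(spec$seed + 1L)
  taxa <- synthetic_taxa(spec)
  phyla <- unique(taxa$phylum)
  families <- unique(db$marker_id)
  K <- length(families)
  T_n <- spec$transcripts_per_sample
  plan <- spec$cross_contam_plan
  if (!is.null(plan)) {
    unknown <- setdiff(c(plan$donor, plan$recipient), taxa$sample_id)
    if (length(unknown) > 0L) {
      stop_config("cross_contam_plan names unknown sample(s): %s",
                  paste(unknown, collapse = ", "))
    }
  }

  frac_of <- function(sid) {
    f <- spec$foreign_marker_fraction
    if (length(f) == 1L && is.null(names(f))) return(unname(f))
    if (sid %in% names(f)) unname(f[sid]) else 0
  }

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "samples"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  truth_foreign <- list()
  truth_dup <- list()
  truth_cc <- list()

  # ---- per-sample base transcripts (markers + background + duplicates)
  transcripts <- list()  # sample_id -> named character vector
  cc_slots <- integer(nrow(taxa))
  names(cc_slots) <- taxa$sample_id
  if (!is.null(plan)) {
    for (r in seq_len(nrow(plan))) {
      cc_slots[plan$recipient[r]] <-
        cc_slots[plan$recipient[r]] + floor(plan$fraction[r] * T_n)
    }
  }

  for (i in seq_len(nrow(taxa))) {
    sid <- taxa$sample_id[i]
    own_ph <- taxa$phylum[i]
    n_foreign <- round(frac_of(sid) * spec$marker_copies)
    if (frac_of(sid) > 0 && n_foreign < 1L) {
      stop_config("foreign_marker_fraction %.3f of %d marker copies plants nothing",
                  frac_of(sid), spec$marker_copies)
    }
    if (n_foreign > 0L && length(phyla) < 2L) {
      stop_config("planting foreign-phylum markers requires at least 2 phyla")
    }
    n_dup <- floor(spec$duplicate_fraction * T_n)
    n_cc <- cc_slots[[sid]]
    n_bg <- T_n - spec$marker_copies - n_dup - n_cc
    if (n_bg < 0L || (n_dup > 0L && n_bg < n_dup)) {
      stop_config(
        "sample %s: infeasible composition (markers %d + duplicates %d + cross-contaminants %d > %d transcripts)",
        sid, spec$marker_copies, n_dup, n_cc, T_n)
    }
    seqs <- character(0)
    # marker-derived transcripts; the last n_foreign are foreign copies
    if (spec$marker_copies > 0L) {
      for (j in seq_len(spec$marker_copies)) {
        fam <- families[(j - 1L) %% K + 1L]
        foreign <- j > spec$marker_copies - n_foreign
        ph <- if (foreign) {
          phyla[(match(own_ph, phyla)) %% length(phyla) + 1L]
        } else own_ph
        res <- db$residues[db$marker_id == fam & db$phylum == ph]
        tid <- sprintf("mk%03d_%s", j, fam)
        seqs[tid] <- reverse_translate(res)
        if (foreign) {
          truth_foreign[[length(truth_foreign) + 1L]] <- data.frame(
            sample_id = sid, transcript_id = tid, marker_id = fam,
            foreign_phylum = ph, stringsAsFactors = FALSE)
        }
      }
    }
    guard <- spec$marker_copies > 0L  # marker screen exercised on this data
    if (n_bg > 0L) {
      lens <- sample(seq(spec$transcript_len[1L], spec$transcript_len[2L]),
                     n_bg, replace = TRUE)
      bg <- random_dna(lens)
      if (guard) {
        bg <- enforce_marker_dissimilar(
          bg, db, spec$marker_max_cross_score,
          redraw = function(i) random_dna(lens[i]), what = "background")
      }
      names(bg) <- sprintf("bg%04d", seq_len(n_bg))
      seqs <- c(seqs, bg)
    }
    if (n_dup > 0L) {
      src_ids <- sprintf("bg%04d", seq_len(n_dup))
      dup_src <- unname(seqs[src_ids])
      n_sub <- pmax(1L, round((1 - spec$duplicate_identity / 100) *
                              nchar(dup_src)))
      dups <- vapply(seq_len(n_dup),
                     function(d) mutate_dna(dup_src[d], n_sub[d]), "")
      if (guard) {
        dups <- enforce_marker_dissimilar(
          dups, db, spec$marker_max_cross_score,
          redraw = function(i) mutate_dna(dup_src[i], n_sub[i]),
          what = "near-duplicate")
      }
      names(dups) <- sprintf("dup%04d", seq_len(n_dup))
      seqs <- c(seqs, dups)
      truth_dup[[length(truth_dup) + 1L]] <- data.frame(
        sample_id = sid, dup_id = names(dups), source_id = src_ids,
        n_sub = n_sub,
        identity_pct = 100 * (1 - n_sub / nchar(dup_src)),
        stringsAsFactors = FALSE)
    }
    transcripts[[sid]] <- seqs
  }

  # ---- cross-contamination planting (donor transcripts now exist)
  cc_ids <- lapply(taxa$sample_id, function(x) character(0))
  names(cc_ids) <- taxa$sample_id
  cc_mult <- lapply(taxa$sample_id, function(x) numeric(0))
  names(cc_mult) <- taxa$sample_id
  if (!is.null(plan)) {
    for (r in seq_len(nrow(plan))) {
      don <- plan$donor[r]; rec <- plan$recipient[r]
      n_cc <- floor(plan$fraction[r] * T_n)
      if (n_cc < 1L) {
        stop_config("cross_contam_plan row %d plants nothing (fraction %.3f of %d)",
                    r, plan$fraction[r], T_n)
      }
      donor_pool <- names(transcripts[[don]])
      donor_pool <- donor_pool[grepl("^bg", donor_pool)]
      if (length(donor_pool) < n_cc) {
        stop_config("donor %s has only %d background transcripts (< %d needed)",
                    don, length(donor_pool), n_cc)
      }
      pick <- donor_pool[seq_len(n_cc)]
      new_ids <- sprintf("cc_%s_%s", don, pick)
      add <- transcripts[[don]][pick]
      names(add) <- new_ids
      transcripts[[rec]] <- c(transcripts[[rec]], add)
      cc_ids[[rec]] <- c(cc_ids[[rec]], new_ids)
      cc_mult[[rec]] <- c(cc_mult[[rec]], rep(plan$depth_mult[r], n_cc))
      truth_cc[[length(truth_cc) + 1L]] <- data.frame(
        donor = don, recipient = rec, transcript_id = new_ids,
        donor_transcript_id = pick, fraction = plan$fraction[r],
        depth_mult = plan$depth_mult[r], stringsAsFactors = FALSE)
    }
  }

  # ---- reads + file output
  manifest <- taxa
  manifest$fasta <- file.path("samples", paste0(taxa$sample_id, ".fasta"))
  manifest$fastq <- file.path("samples", paste0(taxa$sample_id, ".fastq"))

  for (i in seq_len(nrow(taxa))) {
    sid <- taxa$sample_id[i]
    seqs <- transcripts[[sid]]
    stopifnot(length(seqs) == T_n)
    write_fasta(seqs, file.path(dir, "samples", paste0(sid, ".fasta")))

    w <- rep(1, length(seqs))
    names(w) <- names(seqs)
    if (length(cc_ids[[sid]]) > 0L) {
      w[cc_ids[[sid]]] <- 1 / cc_mult[[sid]]
    }
    counts <- as.vector(stats::rmultinom(1L, spec$reads_per_sample, w))
    idx <- rep(seq_along(seqs), counts)
    lens <- nchar(seqs)[idx]
    max_start <- pmax(1L, lens - spec$read_len + 1L)
    starts <- 1L + as.integer(floor(stats::runif(length(idx)) * max_start))
    reads <- substring(seqs[idx], starts,
                       pmin(lens, starts + spec$read_len - 1L))
    rc <- stats::rbinom(length(reads), 1L, 0.5) == 1L
    if (any(rc)) {
      reads[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[rc])))
    }
    if (spec$read_error_rate > 0 && length(reads) > 0L) {
      reads <- vapply(reads, function(r) {
        n_err <- stats::rbinom(1L, nchar(r), spec$read_error_rate)
        if (n_err > 0L) mutate_dna(r, n_err) else r
      }, "", USE.NAMES = FALSE)
    }
    names(reads) <- sprintf("%s_r%06d", sid, seq_along(reads))
    qline <- strrep("I", spec$read_len)
    fq <- file.path(dir, "samples", paste0(sid, ".fastq"))
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n",
                      substr(qline, 1L, nchar(reads))), fq)
  }

  write_marker_db(db, file.path(dir, "markers.faa"))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  bind_or_empty <- function(lst, cols) {
    if (length(lst) > 0L) do.call(rbind, lst)
    else as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                       cols))
  }
  truth <- list(
    planted_crosscontam = bind_or_empty(
      truth_cc, c("donor", "recipient", "transcript_id",
                  "donor_transcript_id", "fraction", "depth_mult")),
    planted_foreign = bind_or_empty(
      truth_foreign, c("sample_id", "transcript_id", "marker_id",
                       "foreign_phylum")),
    planted_duplicates = bind_or_empty(
      truth_dup, c("sample_id", "dup_id", "source_id", "n_sub",
                   "identity_pct")))
  for (nm in names(truth)) {
    utils::write.table(truth[[nm]], file.path(dir, "truth",
                                              paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(manifest = manifest, marker_db = db, truth = truth,
                 dir = dir))
}
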