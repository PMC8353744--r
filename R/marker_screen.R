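#' Translate a nucleotide sequence in all six frames
#'
#' Frames +1, +2, +3 read the forward strand at offsets 0, 1, 2; frames
#' -1, -2, -3 read the reverse complement the same way. Standard genetic
#' code, stop codons rendered `*`, trailing partial codons dropped,
#' codons containing N translated as `X`.
#'
#' @param seq a nucleotide string, [Biostrings::DNAString], or
#'   length-one DNAStringSet.
#' @return a named character vector of six amino-acid strings
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`); short frames may be empty strings.
#' @export
translate_six_frames <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) seq <- seq[[1L]]
  aa <- six_frames_cpp(toupper(as.character(seq)))
  names(aa) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  aa
}

# All six frames for every transcript in a DNAStringSet (or character
# vector). Returns data.frame(transcript (index), frame (label), aa).
six_frames_set <- function(dss) {
  n <- length(dss)
  if (n == 0L) {
    return(data.frame(transcript = integer(), frame = character(),
                      aa = character(), stringsAsFactors = FALSE))
  }
  aa <- six_frames_cpp(as.character(dss))
  labels <- c("+1", "+2", "+3", "-1", "-2", "-3")
  data.frame(
    transcript = rep(seq_len(n), times = 6L),
    frame = rep(labels, each = n),
    aa = aa,
    stringsAsFactors = FALSE
  )
}

#' Optimal local protein alignment
#'
#' Smith-Waterman with Gotoh affine gaps; a gap of length L costs
#' `gap_open + L * gap_ext`. Identity is computed over aligned columns
#' excluding gaps. A best score of 0 means no positive-scoring local
#' alignment exists ("no hit").
#'
#' @param query,ref amino-acid strings (non-empty).
#' @param matrix substitution matrix with single-letter dimnames;
#'   defaults to BLOSUM62.
#' @param gap_open,gap_ext affine gap penalties (positive costs).
#' @return a list: `score`, `identity_pct`, `aligned_length` (number of
#'   aligned columns), `ref_span` (columns covered on the reference),
#'   and the 1-based coordinates of the aligned region.
#' @export
align_protein <- function(query, ref, matrix = NULL, gap_open = 11,
                          gap_ext = 1) {
  if (is.null(matrix)) matrix <- blosum62()
  v <- sw_align_cpp(query, ref, matrix, gap_open, gap_ext)
  list(score = unname(v["score"]),
       identity_pct = if (v["align_cols"] > 0)
         100 * unname(v["matches"]) / unname(v["align_cols"]) else 0,
       aligned_length = unname(v["align_cols"]),
       ref_span = if (v["score"] > 0)
         unname(v["s_end"] - v["s_start"] + 1) else 0,
       q_start = unname(v["q_start"]), q_end = unname(v["q_end"]),
       s_start = unname(v["s_start"]), s_end = unname(v["s_end"]))
}

# Best hit per (transcript, marker family): six-frame translate every
# transcript, align every frame against every reference, keep the best
# (frame x reference) per family. Ties on score break by higher
# identity, then lexicographically smaller ref_id.
# Returns the full per-(transcript, family) best-hit table without
# score/identity filtering (filtering is the caller's policy).
best_marker_hits <- function(transcripts, marker_db, matrix = NULL,
                             gap_open = 11, gap_ext = 1) {
  if (is.null(matrix)) matrix <- blosum62()
  if (nrow(marker_db) == 0L) stop_config("marker database is empty")
  fr <- six_frames_set(transcripts)
  ids <- names(transcripts)
  # bulk score-only pass; full traceback only for per-family winners
  S <- matrix(0, nrow(fr), nrow(marker_db))
  for (r in seq_len(nrow(marker_db))) {
    S[, r] <- sw_score_batch_cpp(fr$aa, marker_db$residues[r], matrix,
                                 gap_open, gap_ext)
  }
  hits <- list()
  families <- unique(marker_db$marker_id)
  for (fam in families) {
    ridx <- which(marker_db$marker_id == fam)
    for (t in seq_along(transcripts)) {
      rows <- which(fr$transcript == t)
      sub <- S[rows, ridx, drop = FALSE]
      top <- max(sub)
      if (top <= 0) next
      cand_idx <- which(sub == top, arr.ind = TRUE)
      best <- NULL
      for (ci in seq_len(nrow(cand_idx))) {
        frow <- rows[cand_idx[ci, 1L]]
        r <- ridx[cand_idx[ci, 2L]]
        v <- sw_align_cpp(fr$aa[frow], marker_db$residues[r], matrix,
                          gap_open, gap_ext)
        cand <- list(score = unname(v["score"]),
                     identity_pct = if (v["align_cols"] > 0)
                       100 * unname(v["matches"]) / unname(v["align_cols"])
                     else 0,
                     align_cols = unname(v["align_cols"]),
                     ref_span = unname(v["s_end"] - v["s_start"] + 1),
                     frame = fr$frame[frow],
                     ref = r)
        if (is.null(best) ||
            cand$identity_pct > best$identity_pct ||
            (cand$identity_pct == best$identity_pct &&
             marker_db$ref_id[cand$ref] < marker_db$ref_id[best$ref])) {
          best <- cand
        }
      }
      if (!is.null(best) && best$score > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          transcript_id = ids[t], marker_id = fam,
          best_phylum = marker_db$phylum[best$ref],
          best_genus = marker_db$genus[best$ref],
          ref_id = marker_db$ref_id[best$ref],
          ref_length = marker_db$ref_length[best$ref],
          frame = best$frame, score = best$score,
          identity_pct = best$identity_pct,
          aligned_length = best$align_cols,
          ref_span = best$ref_span,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(transcript_id = character(), marker_id = character(),
                      best_phylum = character(), best_genus = character(),
                      ref_id = character(), ref_length = integer(),
                      frame = character(), score = numeric(),
                      identity_pct = numeric(), aligned_length = numeric(),
                      ref_span = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Screen a sample's transcripts against a ribosomal-marker database
#'
#' For each transcript and marker family, the best (frame x reference)
#' local alignment is retained iff `score >= min_score` and
#' `identity_pct >= min_identity`. A transcript may hit several marker
#' families (one best hit per family); `best_phylum` is the taxonomy of
#' the winning reference.
#'
#' @param sample a `derepool_sample` (or a list with `sample_id` and
#'   `transcripts`).
#' @param marker_db data.frame from [read_marker_db()].
#' @param min_score minimum retained alignment score.
#' @param min_identity minimum percent identity over aligned columns.
#' @param gap_open,gap_ext affine gap penalties.
#' @return a data.frame of marker hits (sample_id, transcript_id,
#'   marker_id, best_phylum, score, identity_pct, ...).
#' @export
screen_sample <- function(sample, marker_db, min_score = 50,
                          min_identity = 30, gap_open = 11, gap_ext = 1) {
  if (nrow(marker_db) == 0L) stop_config("marker database is empty")
  hits <- best_marker_hits(sample$transcripts, marker_db,
                           gap_open = gap_open, gap_ext = gap_ext)
  hits <- hits[hits$score >= min_score & hits$identity_pct >= min_identity, ,
               drop = FALSE]
  if (nrow(hits) > 0L) {
    hits <- cbind(sample_id = sample$sample_id, hits,
                  stringsAsFactors = FALSE)
  } else {
    hits <- cbind(sample_id = character(0), hits)
  }
  rownames(hits) <- NULL
  hits
}

#' Estimate contamination from marker hits
#'
#' The contamination estimate of a sample is the fraction of its marker
#' hits whose best reference belongs to a foreign phylum. A sample with
#' zero marker hits cannot be scored and is flagged unscorable.
#'
#' @param hits data.frame from [screen_sample()] (all of one sample).
#' @param sample_taxonomy list with at least `phylum`; or a phylum string.
#' @return one-row data.frame: `sample_id`, `n_hits`, `n_foreign`,
#'   `contamination_pct` (NA when unscorable), `unscorable`.
#' @export
estimate_contamination <- function(hits, sample_taxonomy) {
  phylum <- if (is.list(sample_taxonomy)) sample_taxonomy$phylum
            else sample_taxonomy
  sid <- if (nrow(hits) > 0L) unique(hits$sample_id) else NA_character_
  if (length(sid) > 1L) {
    stop_consistency("hits span multiple samples: %s",
                     paste(sid, collapse = ", "))
  }
  n <- nrow(hits)
  nf <- sum(hits$best_phylum != phylum)
  data.frame(
    sample_id = sid,
    n_hits = n,
    n_foreign = nf,
    contamination_pct = if (n > 0L) 100 * nf / n else NA_real_,
    unscorable = n == 0L,
    stringsAsFactors = FALSE
  )
}
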