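#' Phylum-wise outlier detection with a Tukey fence
#'
#' A single global contamination threshold is impracticable when whole
#' phyla differ in their baseline contamination (ciliates being the
#' canonical example), so units are fenced within their own phylum:
#' for every phylum with at least `min_group` scorable units the upper
#' Tukey fence `Q3 + fence_k * IQR` (quartiles by linear interpolation,
#' [stats::quantile] type 7) is computed over the units' metric values,
#' and units strictly above the fence are flagged. Phyla with fewer than
#' `min_group` units are reported unfenced and never flagged: a rare
#' phylum is not discarded on no statistical basis. A MAD-based fence
#' (`median + fence_k * mad`) is available via `method`.
#'
#' @param estimates data.frame with columns `unit_id`, `phylum`, and the
#'   metric column named by `metric` (default `contamination_pct`);
#'   NA metric values (unscorable units) are excluded from fencing and
#'   never flagged.
#' @param fence_k fence multiplier (default 1.5).
#' @param min_group minimum units per phylum for fencing (default 4).
#' @param metric name of the metric column.
#' @param method `"tukey"` (default) or `"mad"`.
#' @return data.frame: unit_id, phylum, metric, value, fence_upper
#'   (NA when unfenced), fenced, flagged.
#' @export
detect_outliers <- function(estimates, fence_k = 1.5, min_group = 4L,
                            metric = "contamination_pct",
                            method = c("tukey", "mad")) {
  method <- match.arg(method)
  if (fence_k <= 0) stop_config("fence_k must be > 0")
  if (min_group < 1L) stop_config("min_group must be >= 1")
  if (nrow(estimates) == 0L) {
    return(data.frame(unit_id = character(), phylum = character(),
                      metric = character(), value = numeric(),
                      fence_upper = numeric(), fenced = logical(),
                      flagged = logical(), stringsAsFactors = FALSE))
  }
  if (!metric %in% names(estimates)) {
    stop_config("metric column '%s' not found", metric)
  }
  out <- data.frame(unit_id = estimates$unit_id,
                    phylum = estimates$phylum,
                    metric = metric,
                    value = estimates[[metric]],
                    fence_upper = NA_real_,
                    fenced = FALSE, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (ph in unique(out$phylum)) {
    rows <- which(out$phylum == ph & !is.na(out$value))
    if (length(rows) < min_group) next
    x <- out$value[rows]
    fence <- if (method == "tukey") {
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      q[2L] + fence_k * (q[2L] - q[1L])
    } else {
      stats::median(x) + fence_k * stats::mad(x)
    }
    out$fence_upper[rows] <- fence
    out$fenced[rows] <- TRUE
    out$flagged[rows] <- out$value[rows] > fence
  }
  out
}

#' Marker-recovery completeness of a transcriptome
#'
#' A lightweight completeness score over the marker database: for each
#' marker family the best transcript hit is found with the marker-screen
#' machinery; a family is `complete` when the alignment covers at least
#' `frag_frac` of the winning reference's length, `fragmented` when a
#' retained hit covers less, and `missing` when no hit passes the
#' score/identity thresholds.
#'
#' @param transcripts named [Biostrings::DNAStringSet] of one unit.
#' @param marker_db data.frame from [read_marker_db()].
#' @param unit_id identifier reported in the output row.
#' @param frag_frac fraction of the reference length required for a
#'   family to count as complete (default 0.7).
#' @param min_score,min_identity hit retention thresholds, as in
#'   [screen_sample()].
#' @return one-row data.frame: unit_id, n_markers, n_complete,
#'   n_fragmented, n_missing, pct_complete.
#' @export
assess_completeness <- function(transcripts, marker_db, unit_id = "unit",
                                frag_frac = 0.7, min_score = 50,
                                min_identity = 30) {
  if (nrow(marker_db) == 0L) stop_config("marker database is empty")
  if (frag_frac <= 0 || frag_frac >= 1) {
    stop_config("frag_frac must be in (0, 1)")
  }
  families <- unique(marker_db$marker_id)
  hits <- best_marker_hits(transcripts, marker_db)
  hits <- hits[hits$score >= min_score & hits$identity_pct >= min_identity, ,
               drop = FALSE]
  n_complete <- 0L
  n_fragmented <- 0L
  for (fam in families) {
    h <- hits[hits$marker_id == fam, , drop = FALSE]
    if (nrow(h) == 0L) next
    h <- h[order(-h$score, -h$identity_pct, h$transcript_id,
                 method = "radix"), , drop = FALSE]
    best <- h[1L, ]
    if (best$ref_span >= frag_frac * best$ref_length) {
      n_complete <- n_complete + 1L
    } else {
      n_fragmented <- n_fragmented + 1L
    }
  }
  n_markers <- length(families)
  data.frame(unit_id = unit_id,
             n_markers = n_markers,
             n_complete = n_complete,
             n_fragmented = n_fragmented,
             n_missing = n_markers - n_complete - n_fragmented,
             pct_complete = 100 * n_complete / n_markers,
             stringsAsFactors = FALSE)
}
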