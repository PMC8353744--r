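#' Build a canonical k-mer index over the pan-assembly
#'
#' All transcripts of all samples are pooled; k-mers are canonicalized
#' (lexicographic minimum of a k-mer and its reverse complement) and
#' k-mers containing N are skipped. Transcripts shorter than k
#' contribute nothing (with a warning).
#'
#' @param samples list of `derepool_sample` objects (or lists with
#'   `sample_id` and `transcripts`).
#' @param k odd k-mer size in `[15, 31]`; default 21.
#' @return an object of class `kmer_index`: the compiled index plus a
#'   catalog data.frame (owner_sample, transcript_id, length).
#' @export
build_kmer_index <- function(samples, k = 21L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 15L || k > 31L) {
    stop_config("k must be odd and in [15, 31], got %d", k)
  }
  catalog <- do.call(rbind, lapply(samples, function(s) {
    data.frame(owner_sample = s$sample_id,
               transcript_id = names(s$transcripts),
               length = Biostrings::width(s$transcripts),
               stringsAsFactors = FALSE)
  }))
  seqs <- unlist(lapply(samples, function(s) as.character(s$transcripts)),
                 use.names = FALSE)
  short <- catalog$length < k
  if (any(short)) {
    warning(sprintf("%d transcript(s) shorter than k=%d contribute no k-mers",
                    sum(short), k))
  }
  ptr <- kx_build(seqs, k)
  structure(list(ptr = ptr, k = k, catalog = catalog,
                 sample_ids = vapply(samples, function(s) s$sample_id, "")),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d transcripts from %d samples, %.0f k-mers\n",
              x$k, nrow(x$catalog), length(x$sample_ids), kx_nkmers(x$ptr)))
  invisible(x)
}

#' Distinct canonical k-mers of a sequence
#'
#' @param seq nucleotide string.
#' @param k k-mer size.
#' @return sorted character vector of distinct canonical k-mers.
#' @export
canonical_kmers <- function(seq, k = 21L) {
  canonical_kmers_cpp(as.character(seq), as.integer(k))
}

#' Look up the posting list of one k-mer
#'
#' @param index a `kmer_index`.
#' @param kmer a k-length nucleotide string (canonicalized internally).
#' @return the catalog rows of the transcripts containing the k-mer.
#' @export
kmer_postings <- function(index, kmer) {
  idx <- kx_postings(index$ptr, kmer)
  index$catalog[idx, , drop = FALSE]
}

#' Attribute one sample's reads across the pan-assembly
#'
#' Each read votes for the transcript(s) maximizing the number of shared
#' distinct canonical k-mers. Reads whose best share is below
#' `min_share` stay unattributed; an m-way tie adds 1/m to each tied
#' transcript. Attribution is deterministic and independent of read
#' order.
#'
#' @param index a `kmer_index` built over ALL samples' transcripts.
#' @param reads DNAStringSet (or character vector) of one sample's reads.
#' @param min_share minimum shared k-mer count for attribution.
#' @return numeric vector of fractional counts, one per catalog row.
#' @export
attribute_reads <- function(index, reads, min_share = 2L) {
  kx_attribute(index$ptr, as.character(reads), as.integer(min_share))
}

#' Length-normalized expression from attributed counts
#'
#' `expr(t) = 1e6 * (count(t)/len_kb(t)) / sum_u(count(u)/len_kb(u))`
#' (TPM-like: a read-sample's attributed expression sums to one
#' million). All-zero counts give all-zero expression.
#'
#' @param counts fractional attributed counts.
#' @param lengths transcript lengths in bases.
#' @return numeric vector of expression values.
#' @export
quantify_expression <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  rate <- counts / (lengths / 1000)
  tot <- sum(rate)
  if (tot <= 0) return(rep(0, length(counts)))
  1e6 * rate / tot
}

#' Classify transcripts as clean / cross-contaminant / dubious / low-expression
#'
#' For a transcript t owned by sample S, let `e_S` be its expression
#' measured with S's own reads and `e_O` the maximum expression measured
#' with any other sample's reads (attained by donor `O*`). Then:
#' both below `min_expr` -> `lowexp`; `e_O >= R * e_S` -> `crosscontam`
#' with donor `O*`; `e_S/R < e_O < R * e_S` (with `e_S > 0`) ->
#' `dubious`; otherwise `clean`.
#'
#' @param expr numeric matrix, rows = catalog transcripts, columns =
#'   read-samples (column names = sample ids).
#' @param catalog the catalog data.frame of a [build_kmer_index()].
#' @param R expression ratio (> 1) declaring a cross-contaminant.
#' @param min_expr expression floor below which a transcript is ignored.
#' @return data.frame of verdicts: owner_sample, transcript_id,
#'   category, donor_sample (NA unless crosscontam), e_own, e_other.
#' @export
classify_transcripts <- function(expr, catalog, R = 2, min_expr = 0.5) {
  if (R <= 1) stop_config("R must be > 1, got %s", format(R))
  if (min_expr < 0) stop_config("min_expr must be >= 0")
  sample_ids <- colnames(expr)
  n <- nrow(catalog)
  stopifnot(nrow(expr) == n)
  e_own <- numeric(n)
  e_oth <- numeric(n)
  donor <- rep(NA_character_, n)
  for (sid in unique(catalog$owner_sample)) {
    rows <- which(catalog$owner_sample == sid)
    own_col <- match(sid, sample_ids)
    e_own[rows] <- expr[rows, own_col]
    other_cols <- setdiff(seq_along(sample_ids), own_col)
    if (length(other_cols) == 0L) {
      e_oth[rows] <- 0
      next
    }
    M <- expr[rows, other_cols, drop = FALSE]
    mx <- apply(M, 1L, max)
    e_oth[rows] <- mx
    am <- max.col(M, ties.method = "first")
    donor[rows] <- sample_ids[other_cols][am]
  }
  category <- rep("clean", n)
  low <- e_own < min_expr & e_oth < min_expr
  cc <- !low & e_oth >= R * e_own & e_oth > 0
  dub <- !low & !cc & e_own > 0 & e_oth > e_own / R & e_oth < R * e_own
  category[low] <- "lowexp"
  category[cc] <- "crosscontam"
  category[dub] <- "dubious"
  donor[category != "crosscontam"] <- NA_character_
  data.frame(owner_sample = catalog$owner_sample,
             transcript_id = catalog$transcript_id,
             category = category, donor_sample = donor,
             e_own = e_own, e_other = e_oth,
             stringsAsFactors = FALSE)
}

#' Directed cross-contamination matrix
#'
#' `cc(A -> B)` is the percentage of B's transcripts carrying a
#' `crosscontam` verdict with donor A. The diagonal is 0 by
#' construction; column sums cannot exceed 100.
#'
#' @param verdicts data.frame from [classify_transcripts()], covering
#'   every transcript of every sample.
#' @param sample_ids the ordered sample ids (matrix row/column order).
#' @return numeric matrix with `cc[A, B] = cc(A -> B)` in percent.
#' @export
cross_contam_matrix <- function(verdicts, sample_ids) {
  n_tr <- table(factor(verdicts$owner_sample, levels = sample_ids))
  if (any(n_tr == 0L)) {
    stop_consistency("sample(s) with zero transcripts in verdicts: %s",
                     paste(names(n_tr)[n_tr == 0L], collapse = ", "))
  }
  m <- matrix(0, length(sample_ids), length(sample_ids),
              dimnames = list(sample_ids, sample_ids))
  cc <- verdicts[verdicts$category == "crosscontam", , drop = FALSE]
  if (nrow(cc) > 0L) {
    tab <- table(factor(cc$donor_sample, levels = sample_ids),
                 factor(cc$owner_sample, levels = sample_ids))
    m <- 100 * sweep(unclass(tab), 2L, as.numeric(n_tr), "/")
  }
  diag(m) <- 0
  m
}

#' Full cross-contamination analysis (CroCo-style read re-attribution)
#'
#' Pools all transcripts, attributes every sample's reads across the
#' pan-assembly, quantifies TPM-like expression per read-sample,
#' classifies every transcript and summarizes the directed
#' cross-contamination matrix. Per-sample attribution is independent, so
#' sample-level parallelism (`threads`) produces bit-identical results
#' to a serial run.
#'
#' @param samples list of `derepool_sample` objects (transcripts and reads).
#' @param k canonical k-mer size (odd, 15-31).
#' @param min_share minimum shared k-mers for read attribution.
#' @param R expression ratio declaring a cross-contaminant.
#' @param min_expr TPM-like expression floor.
#' @param threads number of worker processes for attribution.
#' @return a list: `matrix` (CrossContamMatrix), `verdicts`, `expr`
#'   (transcripts x read-samples), `catalog`.
#' @export
cross_contamination <- function(samples, k = 21L, min_share = 2L, R = 2,
                                min_expr = 0.5, threads = 1L) {
  index <- build_kmer_index(samples, k = k)
  sample_ids <- index$sample_ids
  attribute_one <- function(s) attribute_reads(index, s$reads, min_share)
  counts <- if (threads > 1L) {
    parallel::mclapply(samples, attribute_one, mc.cores = threads)
  } else {
    lapply(samples, attribute_one)
  }
  expr <- vapply(counts, function(cn) quantify_expression(cn, index$catalog$length),
                 numeric(nrow(index$catalog)))
  colnames(expr) <- sample_ids
  counts <- do.call(cbind, counts)
  colnames(counts) <- sample_ids
  verdicts <- classify_transcripts(expr, index$catalog, R = R,
                                   min_expr = min_expr)
  mat <- cross_contam_matrix(verdicts, sample_ids)
  list(matrix = mat, verdicts = verdicts, expr = expr, counts = counts,
       catalog = index$catalog)
}
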