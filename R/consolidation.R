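#' Build a pooling plan from genus membership and cross-contamination
#'
#' Samples whose genus occurs once are `singleton_unique_genus` pools.
#' Within each multi-sample genus an undirected graph is built with an
#' edge between A and B iff the combined cross-contamination value
#' (`max`, `min` or `mean` of the two directions, default `max`) is at
#' least `threshold_pct`; connected components of size >= 2 become
#' `combined` pools and isolated samples become `singleton_unrelated`
#' pools, even though they share the genus. Pool ids are
#' `<genus>_<i>` with components numbered in order of their
#' lexicographically smallest member, so the plan is invariant to input
#' order.
#'
#' @param samples data.frame with columns `sample_id` and `genus` (a
#'   `phylum` column, if present, is carried through).
#' @param matrix directed cross-contamination matrix covering all samples.
#' @param threshold_pct relatedness threshold in percent (default 10).
#' @param rule how the two directed values are combined: "max" (an edge
#'   if either direction passes), "min" (both), or "mean".
#' @return an object of class `pool_plan`: `pools` (pool_id, kind,
#'   n_members, members) and `membership` (sample_id -> pool_id).
#' @export
build_pools <- function(samples, matrix, threshold_pct = 10,
                        rule = c("max", "min", "mean")) {
  rule <- match.arg(rule)
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop_config("threshold_pct must be in (0, 100], got %s",
                format(threshold_pct))
  }
  missing <- setdiff(samples$sample_id, rownames(matrix))
  if (length(missing) > 0L) {
    stop_consistency("sample(s) missing from cross-contamination matrix: %s",
                     paste(missing, collapse = ", "))
  }
  comb <- switch(rule,
    max = pmax(matrix, t(matrix)),
    min = pmin(matrix, t(matrix)),
    mean = (matrix + t(matrix)) / 2)

  samples <- samples[order(samples$sample_id, method = "radix"), ,
                     drop = FALSE]
  pools <- list()
  membership <- list()
  for (g in sort(unique(samples$genus), method = "radix")) {
    ids <- samples$sample_id[samples$genus == g]
    if (length(ids) == 1L) {
      pools[[length(pools) + 1L]] <- data.frame(
        pool_id = paste0(g, "_1"), kind = "singleton_unique_genus",
        n_members = 1L, members = ids, stringsAsFactors = FALSE)
      membership[[length(membership) + 1L]] <- data.frame(
        sample_id = ids, pool_id = paste0(g, "_1"),
        kind = "singleton_unique_genus", stringsAsFactors = FALSE)
      next
    }
    adj <- comb[ids, ids, drop = FALSE] >= threshold_pct
    diag(adj) <- FALSE
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(gr)$membership
    comps <- split(ids, memb)
    # deterministic order: by lexicographically smallest member
    comps <- comps[order(vapply(comps, min, ""), method = "radix")]
    for (i in seq_along(comps)) {
      mem <- sort(comps[[i]], method = "radix")
      kind <- if (length(mem) >= 2L) "combined" else "singleton_unrelated"
      pid <- paste0(g, "_", i)
      pools[[length(pools) + 1L]] <- data.frame(
        pool_id = pid, kind = kind, n_members = length(mem),
        members = paste(mem, collapse = ";"), stringsAsFactors = FALSE)
      membership[[length(membership) + 1L]] <- data.frame(
        sample_id = mem, pool_id = pid, kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  pools <- do.call(rbind, pools)
  membership <- do.call(rbind, membership)
  membership <- membership[order(membership$sample_id, method = "radix"), ,
                           drop = FALSE]
  rownames(pools) <- rownames(membership) <- NULL
  structure(list(pools = pools, membership = membership),
            class = "pool_plan")
}

#' @export
print.pool_plan <- function(x, ...) {
  k <- table(x$pools$kind)
  cat(sprintf("<pool_plan> %d pools over %d samples (%s)\n",
              nrow(x$pools), nrow(x$membership),
              paste(sprintf("%s: %d", names(k), as.integer(k)),
                    collapse = ", ")))
  invisible(x)
}

#' Merge a pool's member transcriptomes
#'
#' Every member transcript appears exactly once, renamed
#' `{pool_id}.{sample_id}.{seq_id}` so provenance survives pooling.
#'
#' @param pool_id the pool identifier.
#' @param member_transcripts named list (by sample_id) of DNAStringSets.
#' @return a single merged [Biostrings::DNAStringSet].
#' @export
merge_pool <- function(pool_id, member_transcripts) {
  if (length(member_transcripts) == 0L) {
    stop_config("pool %s has no member transcript sets", pool_id)
  }
  if (anyDuplicated(names(member_transcripts))) {
    stop_consistency("duplicate member sample ids in pool %s", pool_id)
  }
  parts <- lapply(names(member_transcripts), function(sid) {
    tr <- member_transcripts[[sid]]
    res <- as.character(tr)
    names(res) <- paste(pool_id, sid, names(tr), sep = ".")
    res
  })
  merged <- unlist(parts, use.names = TRUE)
  if (anyDuplicated(names(merged))) {
    stop("internal error: rename collision in pool merge")
  }
  out <- Biostrings::DNAStringSet(merged)
  out
}

#' Pairwise nucleotide identity (CD-HIT convention)
#'
#' Matches in the best local alignment divided by the length of the
#' SHORTER sequence, times 100. Scoring: match +2, mismatch -3 (N always
#' mismatches), gap open 5 / extend 2.
#'
#' @param a,b nucleotide strings or XString objects (non-empty).
#' @param match,mismatch,gap_open,gap_ext alignment scoring.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                              gap_ext = 2) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop_config("pairwise_identity requires non-empty sequences")
  }
  v <- sw_align_cpp(a, b, nuc_matrix(match, mismatch), gap_open, gap_ext)
  100 * unname(v["matches"]) / min(nchar(a), nchar(b))
}

# Shared-word prefilter: a pair whose shorter sequence has length L can
# only reach identity >= t if its alignment leaves at most
# floor(L * (1 - t/100)) shorter-sequence positions unmatched; each such
# position destroys at most `word` words, so a true pair must share at
# least (L - word + 1) - word * (floor(L*(1-t/100)) + 1) distinct words
# (the +1 absorbs rounding). Below-threshold pairs may also pass (the
# filter is one-sided); passing pairs still go through the DP.
required_words <- function(len_short, threshold_pct, word) {
  mism <- floor(len_short * (1 - threshold_pct / 100)) + 1
  max(1, (len_short - word + 1) - word * mism)
}

word_set <- function(s, word) {
  n <- nchar(s)
  if (n < word) return(character(0))
  unique(substring(s, 1:(n - word + 1L), word:n))
}

#' Greedy incremental dereplication at a fixed identity threshold
#'
#' CD-HIT-style: sequences are sorted by length descending (ties broken
#' by lexicographic id) and processed in order; each sequence joins the
#' FIRST existing cluster whose representative passes the shared-word
#' prefilter and has [pairwise_identity()] at or above the threshold,
#' otherwise it founds a new cluster. Representatives are returned in
#' founding order.
#'
#' @param seqs named [Biostrings::DNAStringSet] or character vector.
#' @param identity_threshold_pct identity threshold in percent
#'   (default 95, the usual dereplication operating point).
#' @param word_size word length of the prefilter (default 8).
#' @return a list of class `derep_result`: `clusters` (data.frame:
#'   cluster, seq_id, identity_pct, is_representative), and
#'   `representatives` (ids in founding order).
#' @export
dereplicate <- function(seqs, identity_threshold_pct = 95, word_size = 8L) {
  if (identity_threshold_pct <= 0 || identity_threshold_pct > 100) {
    stop_config("identity threshold must be in (0, 100]")
  }
  res <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) stop_config("dereplicate requires named sequences")
  lens <- nchar(res)
  ord <- order(-lens, ids, method = "radix")
  res <- res[ord]; ids <- ids[ord]; lens <- lens[ord]

  rep_idx <- integer(0)          # indices (into sorted order) of reps
  rep_words <- list()
  assign_cluster <- integer(length(res))
  identity <- numeric(length(res))

  for (i in seq_along(res)) {
    w_i <- word_set(res[i], word_size)
    joined <- FALSE
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      len_short <- min(lens[i], lens[r])
      need <- required_words(len_short, identity_threshold_pct, word_size)
      shared <- sum(w_i %in% rep_words[[ci]])
      if (shared < need) next
      idp <- pairwise_identity(res[i], res[r])
      if (idp >= identity_threshold_pct) {
        assign_cluster[i] <- ci
        identity[i] <- idp
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      rep_idx <- c(rep_idx, i)
      rep_words[[length(rep_idx)]] <- w_i
      assign_cluster[i] <- length(rep_idx)
      identity[i] <- 100
    }
  }
  clusters <- data.frame(
    cluster = assign_cluster,
    seq_id = ids,
    identity_pct = identity,
    is_representative = seq_along(res) %in% rep_idx,
    stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster,
                             -as.integer(clusters$is_representative),
                             clusters$seq_id, method = "radix"), ]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, representatives = ids[rep_idx]),
            class = "derep_result")
}

#' @export
print.derep_result <- function(x, ...) {
  cat(sprintf("<derep_result> %d sequences in %d clusters\n",
              nrow(x$clusters), length(x$representatives)))
  invisible(x)
}

#' Write clusters in a `.clstr`-like TSV layout
#' @param derep a `derep_result`.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(derep, path) {
  utils::write.table(derep$clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
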