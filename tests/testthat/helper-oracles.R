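# Shared fixtures and independent oracles. Oracles are deliberately
# naive (full matrices, no banding, no word filter) and independent of
# the package's C++ kernels.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rand_dna_set <- function(n, len_range) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  out <- vapply(lens, rand_dna, "")
  names(out) <- sprintf("s%03d", seq_len(n))
  out
}

rand_aa <- function(len) {
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aas, len, replace = TRUE), collapse = "")
}

# substitute exactly n_sub positions (distinct, different base/residue)
substitute_n <- function(s, n_sub, alphabet = c("A", "C", "G", "T")) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(length(ch), n_sub)
  for (i in pos) ch[i] <- sample(setdiff(alphabet, ch[i]), 1)
  paste(ch, collapse = "")
}

# Full-matrix Gotoh local alignment score (gap of length L costs
# go + L * ge), written independently of src/sw.cpp.
sw_score_oracle <- function(q, s, mat, go, ge) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      d <- H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]]
      H[i, j] <- max(0, d, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

nuc_score_matrix <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5, 5, dimnames = list(b, b))
  diag(m) <- 2
  m["N", "N"] <- -3
  m
}

# Identity via Biostrings (independent route): matches of the optimal
# local alignment / shorter length.
biostrings_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = nuc_score_matrix(),
    gapOpening = 5, gapExtension = 2)
  100 * Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

# Brute-force greedy clustering: same ordering and first-fit rule as
# dereplicate(), but all-pairs identity through Biostrings and no word
# filter.
derep_oracle <- function(seqs, threshold) {
  ids <- names(seqs)
  lens <- nchar(seqs)
  ord <- order(-lens, ids, method = "radix")
  seqs <- seqs[ord]; ids <- ids[ord]
  reps <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (biostrings_identity(seqs[[i]], seqs[[reps[ci]]]) >= threshold) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  list(assign = stats::setNames(assign, ids), reps = ids[reps])
}

# Sort-and-interpolate quartiles (type-7 semantics, written out by hand)
quartile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# A minimal in-memory sample object
make_sample <- function(id, transcripts, reads = character(0),
                        phylum = "PhyA", genus = "GenA") {
  tr <- Biostrings::DNAStringSet(transcripts)
  rd <- Biostrings::DNAStringSet(reads)
  structure(list(sample_id = id,
                 taxonomy = list(phylum = phylum, genus = genus,
                                 species = paste(genus, "sp"), strain = ""),
                 transcripts = tr, reads = rd),
            class = "derepool_sample")
}
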