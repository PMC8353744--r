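#' Read a sample manifest
#'
#' The manifest is a TSV with header columns `sample_id`, `phylum`,
#' `genus`, `species`, `strain`, `fasta`, `fastq`. TSV (not CSV) so that
#' commas in strain names survive. Sequence files are not touched here:
#' paths are stored and loaded lazily by [load_sample()].
#'
#' @param path path to the manifest TSV.
#' @return a data.frame with one row per sample, in file order. Relative
#'   `fasta`/`fastq` paths are resolved against the manifest's directory.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_format("manifest not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  required <- c("sample_id", "phylum", "genus", "species", "strain",
                "fasta", "fastq")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_format("manifest %s is missing required column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  df <- df[, required, drop = FALSE]
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L) {
    stop_unique("duplicate sample_id in manifest: %s",
                paste(dup, collapse = ", "))
  }
  base <- dirname(normalizePath(path, mustWork = FALSE))
  resolve <- function(p) ifelse(grepl("^(/|~)", p), p, file.path(base, p))
  df$fasta <- resolve(df$fasta)
  df$fastq <- resolve(df$fastq)
  rownames(df) <- NULL
  df
}

#' Read a nucleotide FASTA file
#'
#' Wrapped or single-line records are both accepted; lowercase residues
#' are uppercased. Residues outside `{A,C,G,T,N}` are rejected for
#' nucleotide sets, duplicate ids and empty records are errors.
#'
#' @param path FASTA path (plain or gzipped).
#' @return a named [Biostrings::DNAStringSet]; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop_format("cannot parse FASTA %s: %s",
                                path, conditionMessage(e))
                  })
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_unique("duplicate sequence id in %s: %s", path,
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- toupper(as.character(set))
  if (any(nchar(res) == 0L)) {
    stop_format("empty sequence record in %s (id %s)", path,
                ids[which(nchar(res) == 0L)[1L]])
  }
  bad <- grepl("[^ACGTN]", res)
  if (any(bad)) {
    stop_format("non-ACGTN residues in %s (id %s)", path, ids[which(bad)[1L]])
  }
  out <- Biostrings::DNAStringSet(res)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a [Biostrings::XStringSet] or named character vector.
#' @param path destination path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Four-line records; base qualities are parsed but dropped (no
#' downstream stage consumes them — reads only feed attribution counts).
#'
#' @param path FASTQ path (plain or gzipped).
#' @return a named [Biostrings::DNAStringSet] of reads.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_format("FASTQ not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (length(lines) == 0L) return(Biostrings::DNAStringSet())
  if (length(lines) %% 4L != 0L) {
    stop_format("truncated FASTQ record %d in %s",
                length(lines) %/% 4L + 1L, path)
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = FALSE),
    error = function(e) {
      stop_format("cannot parse FASTQ %s: %s", path, conditionMessage(e))
    })
  names(set) <- sub("\\s.*$", "", names(set))
  set
}

#' Load a sample's sequences from a manifest row
#'
#' @param descriptor a one-row data.frame as returned by [read_manifest()].
#' @return a list with class `derepool_sample`: `sample_id`, `taxonomy`
#'   (list with phylum/genus/species/strain), `transcripts`
#'   (DNAStringSet), `reads` (DNAStringSet).
#' @export
load_sample <- function(descriptor) {
  stopifnot(nrow(descriptor) == 1L)
  structure(list(
    sample_id  = descriptor$sample_id,
    taxonomy   = list(phylum = descriptor$phylum, genus = descriptor$genus,
                      species = descriptor$species, strain = descriptor$strain),
    transcripts = read_fasta(descriptor$fasta),
    reads       = read_fastq(descriptor$fastq)
  ), class = "derepool_sample")
}

#' @export
print.derepool_sample <- function(x, ...) {
  cat(sprintf("<derepool_sample> %s (%s / %s): %d transcripts, %d reads\n",
              x$sample_id, x$taxonomy$phylum, x$taxonomy$genus,
              length(x$transcripts), length(x$reads)))
  invisible(x)
}

#' Read a taxon-labelled protein marker database
#'
#' Headers follow the pipe-delimited dialect `markerID|phylum|genus|refID`.
#' Residues must be over the 20-letter amino-acid alphabet plus X.
#'
#' @param path FASTA path of protein marker references.
#' @return a data.frame with columns `marker_id`, `phylum`, `genus`,
#'   `ref_id`, `residues`, `ref_length`.
#' @export
read_marker_db <- function(path) {
  if (!file.exists(path)) stop_format("marker FASTA not found: %s", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  parts <- strsplit(names(set), "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    stop_format("marker header not in markerID|phylum|genus|refID form: %s",
                names(set)[which(nf != 4L)[1L]])
  }
  res <- toupper(as.character(set))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", res)
  if (any(bad)) {
    stop_format("non amino-acid residues in marker %s",
                names(set)[which(bad)[1L]])
  }
  m <- do.call(rbind, parts)
  df <- data.frame(marker_id = m[, 1L], phylum = m[, 2L], genus = m[, 3L],
                   ref_id = m[, 4L], residues = unname(res),
                   ref_length = nchar(res), stringsAsFactors = FALSE)
  if (anyDuplicated(df$ref_id)) {
    stop_unique("duplicate marker ref_id: %s",
                paste(unique(df$ref_id[duplicated(df$ref_id)]), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a marker database back to FASTA with structured headers
#' @param db a marker data.frame as from [read_marker_db()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_marker_db <- function(db, path) {
  seqs <- db$residues
  names(seqs) <- paste(db$marker_id, db$phylum, db$genus, db$ref_id, sep = "|")
  write_fasta(seqs, path)
}
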