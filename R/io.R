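#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. Record ids are
#' the first whitespace-delimited token of each header and must be
#' unique within the file.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a valid FASTA file: ", path, " (", conditionMessage(e), ")")
  )
  if (length(x) == 0) stop("FASTA format error: no records in ", path)
  seqs <- chartr("Uu", "Tt", as.character(x))
  seqs <- toupper(seqs)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA format error: empty record id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(nchar(seqs) < 1)) stop("FASTA format error: zero-length sequence in ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (!inherits(seqs, "XStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (is.null(names(seqs))) stop("sequences must be named")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# Strip a mate suffix ("/1", "/2", or anything after whitespace) from a
# FASTQ read id.
strip_mate_suffix <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

#' Read a pair of FASTQ files into a read-pair table
#'
#' Mates are matched by record order; `pair_id` is the read id with its
#' mate suffix (`/1`, `/2` or a space-delimited tag) removed, and must
#' agree between the two files.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2 (phred+33).
#' @return A data.frame with columns `pair_id`, `read1`, `read2`,
#'   `quality1`, `quality2`.
#' @export
read_paired_fastq <- function(path1, path2) {
  for (p in c(path1, path2)) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
  }
  x1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  x2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(x1) != length(x2)) {
    stop("mate file record counts differ: ", length(x1), " vs ", length(x2))
  }
  id1 <- strip_mate_suffix(names(x1))
  id2 <- strip_mate_suffix(names(x2))
  bad <- which(id1 != id2)
  if (length(bad) > 0) {
    stop("read id mismatch at record ", bad[1], ": '", id1[bad[1]], "' vs '", id2[bad[1]], "'")
  }
  data.frame(
    pair_id = id1,
    read1 = unname(as.character(x1)),
    read2 = unname(as.character(x2)),
    quality1 = unname(as.character(S4Vectors::mcols(x1)$qualities)),
    quality2 = unname(as.character(S4Vectors::mcols(x2)$qualities)),
    stringsAsFactors = FALSE
  )
}

#' Write a read-pair table to two FASTQ files
#'
#' @param pairs Data.frame as returned by [read_paired_fastq()];
#'   missing qualities are written as maximal phred+33 (`I`).
#' @param path1,path2 Output FASTQ paths for mate 1 and mate 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_paired_fastq <- function(pairs, path1, path2) {
  write_one <- function(reads, quals, ids, suffix, path) {
    s <- Biostrings::DNAStringSet(reads)
    names(s) <- paste0(ids, suffix)
    if (is.null(quals) || all(is.na(quals))) {
      quals <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    }
    quals[is.na(quals)] <- strrep("I", nchar(reads[is.na(quals)]))
    Biostrings::writeXStringSet(s, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(pairs$read1, pairs$quality1, pairs$pair_id, "/1", path1)
  write_one(pairs$read2, pairs$quality2, pairs$pair_id, "/2", path2)
  invisible(c(path1, path2))
}

#' Parse BLAST tabular (outfmt 6) alignments
#'
#' Reads the standard 12-column tab-separated BLAST output (qseqid
#' sseqid pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore). File coordinates are 1-based inclusive; they are
#' converted to the package's 0-based half-open convention. A subject
#' interval written descending (sstart > send) denotes a minus-strand
#' hit and is stored ascending with `strand == "-"`.
#'
#' @param path Path to a BLAST tabular file.
#' @return A data.frame of hits with columns `query_id`, `subject_id`,
#'   `percent_identity`, `aligned_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`,
#'   `strand`, `evalue`, `bit_score`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad) > 0) {
    stop("BLAST tabular parse error at line ", bad[1], ": expected 12 columns, found ", nf[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  qstart <- as.integer(m[, 7]); qend <- as.integer(m[, 8])
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  minus <- sstart > send
  s_lo <- ifelse(minus, send, sstart)
  s_hi <- ifelse(minus, sstart, send)
  data.frame(
    query_id = m[, 1],
    subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    aligned_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gap_opens = as.integer(m[, 6]),
    query_start = qstart - 1L,
    query_end = qend,
    subject_start = s_lo - 1L,
    subject_end = s_hi,
    strand = ifelse(minus, "-", "+"),
    evalue = as.numeric(m[, 11]),
    bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
}

empty_hits <- function() {
  data.frame(
    query_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), aligned_length = integer(0),
    mismatches = integer(0), gap_opens = integer(0),
    query_start = integer(0), query_end = integer(0),
    subject_start = integer(0), subject_end = integer(0),
    strand = character(0), evalue = numeric(0), bit_score = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Write alignments back to BLAST tabular (outfmt 6)
#'
#' Inverse of [read_blast_tabular()]: internal 0-based half-open
#' coordinates become 1-based inclusive, and minus-strand hits are
#' written with descending subject coordinates.
#'
#' @param hits Hit data.frame in the internal convention.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  minus <- hits$strand == "-"
  sstart <- ifelse(minus, hits$subject_end, hits$subject_start + 1L)
  send <- ifelse(minus, hits$subject_start + 1L, hits$subject_end)
  lines <- paste(
    hits$query_id, hits$subject_id,
    format(hits$percent_identity, trim = TRUE),
    hits$aligned_length, hits$mismatches, hits$gap_opens,
    hits$query_start + 1L, hits$query_end,
    sstart, send,
    format(hits$evalue, trim = TRUE),
    format(hits$bit_score, trim = TRUE),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}
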