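#' Build an exact full-read match index over contaminant references
#'
#' Indexes every substring of length `w` (the read length) of each
#' reference and of its reverse complement, realising a zero-mismatch
#' single-read screen: a read of length `w` matches iff it occurs
#' exactly, on either strand, in a reference. Words containing `N` are
#' excluded, so reads with `N` never match (conservative filtering).
#'
#' @param references Named character vector or DNAStringSet.
#' @param w Word size; must equal the read length of the pairs to be
#'   screened and be no longer than the shortest reference.
#' @return An object of class `exact_match_index`.
#' @export
build_exact_index <- function(references, w) {
  refs <- as.character(references)
  if (length(refs) == 0) stop("no references supplied")
  w <- as.integer(w)
  if (any(nchar(refs) < w)) {
    stop("index word size ", w, " exceeds the shortest reference (",
         min(nchar(refs)), " bp)")
  }
  km <- unlist(lapply(refs, seq_kmers, k = w), use.names = FALSE)
  km <- unique(km)
  km <- km[!grepl("N", km, fixed = TRUE)]
  km <- unique(c(km, revcomp(km)))
  structure(list(ids = names(refs), w = w, words = km),
            class = "exact_match_index")
}

#' Query an exact-match index
#'
#' @param index An [build_exact_index()] object.
#' @param reads Character vector of reads, each exactly `index$w` long.
#' @return Logical vector: does each read occur exactly (either
#'   strand) in the indexed references? The answer is identical for a
#'   read and its reverse complement.
#' @export
index_member <- function(index, reads) {
  stopifnot(inherits(index, "exact_match_index"))
  if (length(reads) == 0) return(logical(0))
  if (any(nchar(reads) != index$w)) {
    stop("reads must all have length ", index$w, " (the index word size)")
  }
  reads %in% index$words
}

#' Remove contaminated read pairs (pair-atomic)
#'
#' A pair is removed iff either read, at full length and with zero
#' mismatches on either strand, occurs in a contaminant reference.
#' Removal is pair-atomic: one matching read discards both mates. When
#' a pair matches both references the vector class takes precedence,
#' so class counts are deterministic.
#'
#' @param pairs Read-pair data.frame (`read1`, `read2`, ...).
#' @param ecoli_index,vector_index [build_exact_index()] objects built
#'   at `w` = the read length.
#' @return List: `kept` (surviving pairs), `input_pairs`,
#'   `removed_vector_pairs`, `removed_ecoli_pairs`, and `removed_class`
#'   (per-input-pair factor: `kept`, `vector`, `ecoli`).
#' @export
filter_contaminant_pairs <- function(pairs, ecoli_index, vector_index) {
  n <- nrow(pairs)
  if (n == 0) {
    return(list(kept = pairs, input_pairs = 0L,
                removed_vector_pairs = 0L, removed_ecoli_pairs = 0L,
                removed_class = character(0)))
  }
  v_hit <- index_member(vector_index, pairs$read1) |
    index_member(vector_index, pairs$read2)
  e_hit <- index_member(ecoli_index, pairs$read1) |
    index_member(ecoli_index, pairs$read2)
  rm_vector <- v_hit
  rm_ecoli <- !v_hit & e_hit
  cls <- rep("kept", n)
  cls[rm_ecoli] <- "ecoli"
  cls[rm_vector] <- "vector"
  list(
    kept = pairs[cls == "kept", , drop = FALSE],
    input_pairs = n,
    removed_vector_pairs = sum(rm_vector),
    removed_ecoli_pairs = sum(rm_ecoli),
    removed_class = cls
  )
}

#' Remove clonal (duplicate) read pairs
#'
#' Two pairs are clonal duplicates when their `(read1, read2)` byte
#' sequences are identical, or identical after swapping mates and
#' reverse-complementing both (the same fragment sequenced from the
#' other strand). The first pair in input order is kept as the
#' representative.
#'
#' @param pairs Read-pair data.frame.
#' @return List: `kept` (deduplicated pairs), `clonal_pairs` (count
#'   removed), `is_clonal` (logical per input pair).
#' @export
remove_clonal_pairs <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0) {
    return(list(kept = pairs, clonal_pairs = 0L, is_clonal = logical(0)))
  }
  k1 <- paste(pairs$read1, pairs$read2, sep = "|")
  k2 <- paste(revcomp(pairs$read2), revcomp(pairs$read1), sep = "|")
  canon <- pmin(k1, k2)
  dup <- duplicated(canon)
  list(kept = pairs[!dup, , drop = FALSE],
       clonal_pairs = sum(dup),
       is_clonal = dup)
}

#' Per-unit sequence coverage estimate
#'
#' Coverage is expressed per cloning unit: total bases divided by the
#' number of BACs times a nominal unit length (120 kb by default),
#' reported to the nearest integer fold.
#'
#' @param total_bases Total sequenced bases.
#' @param n_bacs Number of BACs the bases are spread over.
#' @param unit_length Nominal BAC length in bp.
#' @return Coverage in x-fold, rounded to the nearest integer.
#' @export
estimate_coverage <- function(total_bases, n_bacs, unit_length = 120000) {
  if (n_bacs <= 0 || unit_length <= 0) stop("n_bacs and unit_length must be positive")
  if (total_bases < 0) stop("total_bases must be non-negative")
  round(total_bases / (n_bacs * unit_length))
}

#' Run the full pre-processing QC on a set of read pairs
#'
#' Applies pair-atomic contaminant filtering (vector precedence, then
#' E. coli) followed by clonal-duplicate removal, and reports the
#' pre-processing statistics: per-class removal percentages of input
#' pairs and the raw/filtered per-BAC coverage.
#'
#' @param pairs Read-pair data.frame.
#' @param ecoli_ref,vector_ref Contaminant references (character or
#'   DNAStringSet, single sequence each or several).
#' @param n_bacs Number of BACs in the pool (for coverage accounting).
#' @param unit_length Nominal BAC length (bp).
#' @return List of class `qc_report` with fields `input_pairs`,
#'   `removed_vector_pairs`, `removed_ecoli_pairs`,
#'   `removed_clonal_pairs`, `kept_pairs`, `vector_pct`, `ecoli_pct`,
#'   `clonal_pct`, `raw_coverage`, `filtered_coverage`, and `kept`
#'   (the surviving pairs).
#' @export
run_readqc <- function(pairs, ecoli_ref, vector_ref, n_bacs = 1L,
                       unit_length = 120000) {
  if (nrow(pairs) == 0) stop("no read pairs supplied")
  w <- nchar(pairs$read1[1])
  if (any(nchar(pairs$read1) != w) || any(nchar(pairs$read2) != w)) {
    stop("all reads must share one read length for the exact screen")
  }
  e_idx <- build_exact_index(ecoli_ref, w)
  v_idx <- build_exact_index(vector_ref, w)
  filt <- filter_contaminant_pairs(pairs, e_idx, v_idx)
  dedup <- remove_clonal_pairs(filt$kept)
  input <- filt$input_pairs
  report <- structure(list(
    input_pairs = input,
    removed_vector_pairs = filt$removed_vector_pairs,
    removed_ecoli_pairs = filt$removed_ecoli_pairs,
    removed_clonal_pairs = dedup$clonal_pairs,
    kept_pairs = nrow(dedup$kept),
    vector_pct = 100 * filt$removed_vector_pairs / input,
    ecoli_pct = 100 * filt$removed_ecoli_pairs / input,
    clonal_pct = 100 * dedup$clonal_pairs / input,
    raw_coverage = estimate_coverage(2 * w * input, n_bacs, unit_length),
    filtered_coverage = estimate_coverage(2 * w * nrow(dedup$kept), n_bacs, unit_length),
    read_length = w,
    kept = dedup$kept
  ), class = "qc_report")
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Pre-processing QC report\n")
  cat(sprintf("  input pairs     : %d\n", x$input_pairs))
  cat(sprintf("  vector removed  : %d (%.2f %%)\n", x$removed_vector_pairs, x$vector_pct))
  cat(sprintf("  E. coli removed : %d (%.2f %%)\n", x$removed_ecoli_pairs, x$ecoli_pct))
  cat(sprintf("  clonal removed  : %d (%.2f %%)\n", x$removed_clonal_pairs, x$clonal_pct))
  cat(sprintf("  kept pairs      : %d\n", x$kept_pairs))
  cat(sprintf("  coverage        : %dx raw, %dx filtered\n",
              x$raw_coverage, x$filtered_coverage))
  invisible(x)
}

#' Write a QC report as a one-row TSV
#'
#' Columns mirror the pre-processing statistics table: coverage before
#' and after filtering and the vector / E. coli / clonal percentages.
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @param name Sample name for the first column.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path, name = "sample") {
  df <- data.frame(
    name = name,
    raw_coverage_x = report$raw_coverage,
    vector_pct = round(report$vector_pct, 2),
    ecoli_pct = round(report$ecoli_pct, 2),
    clonal_pct = round(report$clonal_pct, 2),
    filtered_coverage_x = report$filtered_coverage,
    input_pairs = report$input_pairs,
    kept_pairs = report$kept_pairs,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
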