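#' Classify the mapping orientation of mate pairs
#'
#' Both mates must map to the same contig. Mates are ordered by
#' leftmost start (ties by mate number); the class is read off the
#' strand pattern of the leftmost/rightmost mate: `RF` (outward,
#' leftmost minus / rightmost plus — the expected mate-pair class
#' after circularisation), `FR` (inward — the shadow-library class),
#' and `FF_RR` (same-facing — chimeric junction artefacts). The insert
#' size is the outer distance, rightmost end minus leftmost start.
#'
#' @param mapped_pairs Data.frame with columns `contig1`, `start1`,
#'   `end1`, `strand1`, `contig2`, `start2`, `end2`, `strand2`
#'   (0-based half-open).
#' @return Data.frame `(class, insert_size)`, one row per pair, with
#'   `class` in RF/FR/FF_RR.
#' @export
classify_orientation <- function(mapped_pairs) {
  p <- mapped_pairs
  if (nrow(p) == 0) {
    return(data.frame(class = character(0), insert_size = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (any(p$contig1 != p$contig2)) {
    stop("both mates must map to the same contig; use the link path for inter-contig pairs")
  }
  one_left <- p$start1 <= p$start2  # ties: mate 1 counts as leftmost
  ls <- ifelse(one_left, p$strand1, p$strand2)
  rs <- ifelse(one_left, p$strand2, p$strand1)
  left_start <- pmin(p$start1, p$start2)
  right_end <- ifelse(one_left, p$end2, p$end1)
  cls <- ifelse(ls == rs, "FF_RR", ifelse(ls == "-", "RF", "FR"))
  data.frame(class = cls,
             insert_size = as.integer(right_end - left_start),
             stringsAsFactors = FALSE)
}

#' Select mate pairs eligible for orientation validation
#'
#' Keeps pairs in which each mate maps exactly once, with 100 %
#' identity, read length above `min_read_len`, and both mates on the
#' same contig.
#'
#' @param mapped_pairs Data.frame with per-mate columns `hit_count1`,
#'   `hit_count2`, `identity1`, `identity2`, `read_len1`, `read_len2`,
#'   `contig1`, `contig2`.
#' @param min_read_len Minimum read length (strict), 100 bp default.
#' @return The qualifying subset.
#' @export
select_validation_pairs <- function(mapped_pairs, min_read_len = 100) {
  p <- mapped_pairs
  keep <- p$hit_count1 == 1 & p$hit_count2 == 1 &
    p$identity1 == 100 & p$identity2 == 100 &
    p$read_len1 > min_read_len & p$read_len2 > min_read_len &
    p$contig1 == p$contig2
  p[keep, , drop = FALSE]
}

#' Orientation class summary
#'
#' @param calls Output of [classify_orientation()].
#' @return Data.frame with one row per class (RF, FR, FF_RR always
#'   present): `n`, `pct` (of all calls; percentages sum to 100), and
#'   `median_insert` (NA for empty classes).
#' @export
orientation_summary <- function(calls) {
  if (nrow(calls) == 0) stop("no orientation calls to summarise")
  classes <- c("RF", "FR", "FF_RR")
  n <- vapply(classes, function(k) sum(calls$class == k), numeric(1))
  med <- vapply(classes, function(k) {
    v <- calls$insert_size[calls$class == k]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  data.frame(class = classes,
             n = as.integer(n),
             pct = 100 * n / nrow(calls),
             median_insert = med,
             stringsAsFactors = FALSE)
}

#' Select mate pairs usable for scaffolding
#'
#' Keeps pairs in which both mates map with 100 % identity over their
#' full read length and land within the same pool (on any contigs of
#' that pool).
#'
#' @param mapped_pairs Data.frame with `identity1`, `identity2`,
#'   `aligned1`, `aligned2`, `contig1`, `contig2`.
#' @param read_length Full read length (bp); the aligned length of
#'   each mate must equal it.
#' @param contig_pool Named character mapping contig id -> pool id.
#'   When `NULL`, all contigs are assumed to belong to one pool.
#' @return The qualifying subset.
#' @export
select_scaffold_pairs <- function(mapped_pairs, read_length,
                                  contig_pool = NULL) {
  p <- mapped_pairs
  keep <- p$identity1 == 100 & p$identity2 == 100 &
    p$aligned1 == read_length & p$aligned2 == read_length
  if (!is.null(contig_pool)) {
    unknown <- setdiff(unique(c(p$contig1, p$contig2)), names(contig_pool))
    if (length(unknown) > 0) {
      stop("contig(s) with no pool assignment: ", paste(unknown, collapse = ", "))
    }
    keep <- keep & contig_pool[p$contig1] == contig_pool[p$contig2]
  }
  p[keep, , drop = FALSE]
}

#' Build scaffold links from selected pairs
#'
#' One link per selected pair, carrying each mate's contig, interval
#' and strand. Intra-contig pairs are retained (SSPACE uses them for
#' insert-size calibration) but only inter-contig links participate in
#' bundling.
#'
#' @param pairs Selected mate pairs (see [select_scaffold_pairs()])
#'   with per-mate `contig`, `start`, `end`, `strand` columns.
#' @return Data.frame `(pair_id, contig_a, start_a, end_a, strand_a,
#'   contig_b, start_b, end_b, strand_b)`.
#' @export
make_scaffold_links <- function(pairs) {
  data.frame(
    pair_id = pairs$pair_id,
    contig_a = pairs$contig1, start_a = pairs$start1,
    end_a = pairs$end1, strand_a = pairs$strand1,
    contig_b = pairs$contig2, start_b = pairs$start2,
    end_b = pairs$end2, strand_b = pairs$strand2,
    stringsAsFactors = FALSE
  )
}

#' Write links as an SSPACE tab file
#'
#' Standard 6-column tab dialect: `contig_a start_a end_a contig_b
#' start_b end_b`, 1-based inclusive coordinates, one line per pair,
#' deterministically ordered by contig pair then position.
#'
#' @param links Output of [make_scaffold_links()].
#' @param path Output path.
#' @param contig_lengths Optional named numeric; when given, link
#'   contigs are validated against it.
#' @return `path`, invisibly.
#' @export
write_sspace_tab <- function(links, path, contig_lengths = NULL) {
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(unique(c(links$contig_a, links$contig_b)),
                       names(contig_lengths))
    if (length(unknown) > 0) {
      stop("link references unknown contig(s): ", paste(unknown, collapse = ", "))
    }
  }
  if (nrow(links) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ord <- order(links$contig_a, links$contig_b, links$start_a, links$start_b)
  l <- links[ord, ]
  lines <- paste(l$contig_a, l$start_a + 1L, l$end_a,
                 l$contig_b, l$start_b + 1L, l$end_b, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Bundle inter-contig links and estimate gaps
#'
#' Links are grouped by unordered contig pair plus the implied
#' relative orientation (the strand pattern of the two mates on the
#' lexicographically ordered pair). Bundles supported by fewer than
#' `min_links` pairs are dropped — the scaffolder's K threshold.
#' Per link, each mate's span to its gap-facing contig end is
#' `contig_length - start` for a minus-strand mate (gap to its right)
#' and `end` for a plus-strand mate (gap to its left); the gap
#' estimate is the median over links of `insert_mean - span_a -
#' span_b`, with `insert_mean` the midpoint of `insert_range`.
#'
#' @param links Output of [make_scaffold_links()]; intra-contig links
#'   are ignored.
#' @param contig_lengths Named numeric contig lengths.
#' @param min_links Minimum pairs per bundle (default 10, the K value
#'   passed to the scaffolder).
#' @param insert_range Two-element numeric: library insert range in bp
#'   (default 4000-9000, as passed to the scaffolder).
#' @return Data.frame `(contig_a, contig_b, orientation, n_links,
#'   gap_estimate)`, one row per surviving bundle.
#' @export
bundle_links <- function(links, contig_lengths, min_links = 10,
                         insert_range = c(4000, 9000)) {
  inter <- links[links$contig_a != links$contig_b, , drop = FALSE]
  empty <- data.frame(contig_a = character(0), contig_b = character(0),
                      orientation = character(0), n_links = integer(0),
                      gap_estimate = numeric(0), stringsAsFactors = FALSE)
  if (nrow(inter) == 0) return(empty)
  unknown <- setdiff(unique(c(inter$contig_a, inter$contig_b)),
                     names(contig_lengths))
  if (length(unknown) > 0) {
    stop("link references unknown contig(s): ", paste(unknown, collapse = ", "))
  }
  insert_mean <- mean(insert_range)
  # canonical order: lexicographically smaller contig first
  swap <- inter$contig_a > inter$contig_b
  ca <- ifelse(swap, inter$contig_b, inter$contig_a)
  cb <- ifelse(swap, inter$contig_a, inter$contig_b)
  sa <- ifelse(swap, inter$start_b, inter$start_a)
  ea <- ifelse(swap, inter$end_b, inter$end_a)
  ka <- ifelse(swap, inter$strand_b, inter$strand_a)
  sb <- ifelse(swap, inter$start_a, inter$start_b)
  eb <- ifelse(swap, inter$end_a, inter$end_b)
  kb <- ifelse(swap, inter$strand_a, inter$strand_b)
  span_a <- ifelse(ka == "-", contig_lengths[ca] - sa, ea)
  span_b <- ifelse(kb == "-", contig_lengths[cb] - sb, eb)
  gap <- insert_mean - span_a - span_b
  key <- paste(ca, cb, ka, kb, sep = "\r")
  groups <- split(gap, key)
  keep <- names(groups)[lengths(groups) >= min_links]
  if (length(keep) == 0) return(empty)
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(
    contig_a = vapply(parts, `[`, character(1), 1),
    contig_b = vapply(parts, `[`, character(1), 2),
    orientation = vapply(parts, function(x) paste0(x[3], x[4]), character(1)),
    n_links = as.integer(lengths(groups)[keep]),
    gap_estimate = vapply(groups[keep], stats::median, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$contig_a, out$contig_b), , drop = FALSE]
}

#' Write an orientation summary as TSV
#'
#' @param summary Output of [orientation_summary()].
#' @param path Output path.
#' @param reference Label for the reference column.
#' @return `path`, invisibly.
#' @export
write_orientation_summary <- function(summary, path, reference = "contigs") {
  df <- cbind(reference = reference, summary)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-class insert-size histogram
#'
#' @param calls Output of [classify_orientation()].
#' @param binwidth Histogram bin width in bp.
#' @return Data.frame `(class, bin_start, count)`.
#' @export
insert_histogram <- function(calls, binwidth = 250) {
  if (nrow(calls) == 0) {
    return(data.frame(class = character(0), bin_start = numeric(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  bin <- floor(calls$insert_size / binwidth) * binwidth
  agg <- stats::aggregate(list(count = rep(1L, nrow(calls))),
                          by = list(class = calls$class, bin_start = bin), FUN = sum)
  agg[order(agg$class, agg$bin_start), ]
}
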