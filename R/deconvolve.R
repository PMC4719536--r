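#' Shortest distance from a hit to a contig edge
#'
#' @param subject_start,subject_end 0-based half-open hit interval on
#'   the contig.
#' @param contig_length Contig length (bp).
#' @return `min(subject_start, contig_length - subject_end)` — the
#'   shortest distance from the aligned interval to either contig
#'   edge. Vectorised.
#' @export
edge_distance <- function(subject_start, subject_end, contig_length) {
  if (any(subject_start < 0 | subject_end > contig_length |
            subject_start >= subject_end)) {
    stop("hit interval outside [0, contig_length]")
  }
  pmin(subject_start, contig_length - subject_end)
}

#' Build a BES query table from simulated clones
#'
#' @param clones List of [simulate_clone()] objects.
#' @return Data.frame `(bes_id, clone_id, end, sequence, source)` with
#'   one forward and one reverse Sanger BES per clone.
#' @export
bes_queries_from_clones <- function(clones) {
  do.call(rbind, lapply(clones, function(cl) {
    data.frame(
      bes_id = paste0(cl$clone_id, c("_For", "_Rev")),
      clone_id = cl$clone_id,
      end = c("forward", "reverse"),
      sequence = c(cl$bes_forward, cl$bes_reverse),
      source = "sanger_bes",
      stringsAsFactors = FALSE
    )
  }))
}

#' Vector-end proxy queries for clones lacking BES
#'
#' When a clone has no Sanger BES, the terminal 120 bp of the cloning
#' vector on each side of the insertion site serve as proxies: in a
#' correct assembly they sit at the outermost contig ends of that
#' clone. Proxies are exactly 120 bp and bypass the BES length filter
#' (they are flagged in reports).
#'
#' @param vector_seq The cloning-vector backbone sequence.
#' @param proxy_length Proxy length (bp), 120 by default.
#' @return Data.frame in the [bes_queries_from_clones()] layout with
#'   `source = "vector_end_proxy"` and ids `vectorFOR` / `vectorREV`.
#' @export
make_vector_end_proxies <- function(vector_seq, proxy_length = 120L) {
  v <- as.character(vector_seq)[1]
  if (nchar(v) < 2L * proxy_length) stop("vector sequence shorter than two proxies")
  data.frame(
    bes_id = c("vectorFOR", "vectorREV"),
    clone_id = NA_character_,
    end = c("forward", "reverse"),
    sequence = c(substr(v, nchar(v) - proxy_length + 1L, nchar(v)),
                 revcomp(substr(v, 1L, proxy_length))),
    source = "vector_end_proxy",
    stringsAsFactors = FALSE
  )
}

#' Score the hits of one BES and pick its position
#'
#' Each hit is scored `S = bit_score - d_s`, where `d_s` is the
#' shortest distance from the hit to a contig edge: among the many
#' repeat-driven placements of a BAC-end read, the true one lies at a
#' contig end, so proximity to an edge is rewarded. The BES is only
#' eligible when its length exceeds `min_len` and is below `max_len`
#' (Sanger-quality bounds); vector-end proxies bypass this filter.
#' Ties on `S` break by higher bit score, then smaller `d_s`, then
#' lexicographic contig id.
#'
#' @param hits Hit data.frame (see [read_blast_tabular()]) — all rows
#'   must share one `query_id`.
#' @param contig_lengths Named numeric: contig id -> length.
#' @param bes_length Length of the BES query (bp).
#' @param min_len,max_len Eligibility bounds: require
#'   `min_len < bes_length < max_len`.
#' @param length_exempt If `TRUE` the length filter is skipped (used
#'   for 120 bp vector-end proxies).
#' @return One-row data.frame `(bes_id, contig_id, subject_start,
#'   subject_end, strand, d_s, score, competing_hits)`, or `NULL` when
#'   the BES is filtered out or has no hits.
#' @export
score_bes_hits <- function(hits, contig_lengths, bes_length,
                           min_len = 120, max_len = 1000,
                           length_exempt = FALSE) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  if (length(unique(hits$query_id)) != 1) {
    stop("score_bes_hits expects hits of a single BES query")
  }
  if (!length_exempt && (bes_length <= min_len || bes_length >= max_len)) {
    return(NULL)
  }
  unknown <- setdiff(unique(hits$subject_id), names(contig_lengths))
  if (length(unknown) > 0) {
    stop("hit references unknown contig(s): ", paste(unknown, collapse = ", "))
  }
  len <- contig_lengths[hits$subject_id]
  d_s <- edge_distance(hits$subject_start, hits$subject_end, len)
  score <- hits$bit_score - d_s
  ord <- order(-score, -hits$bit_score, d_s, hits$subject_id)
  i <- ord[1]
  data.frame(
    bes_id = hits$query_id[i],
    contig_id = hits$subject_id[i],
    subject_start = hits$subject_start[i],
    subject_end = hits$subject_end[i],
    strand = hits$strand[i],
    d_s = as.numeric(d_s[i]),
    score = as.numeric(score[i]),
    competing_hits = nrow(hits),
    stringsAsFactors = FALSE
  )
}

#' Assign every BES of a query table to its best contig position
#'
#' @param bes_queries BES table (`bes_id`, `clone_id`, `end`,
#'   `sequence`, `source`).
#' @param hits Hit data.frame covering any subset of the queries.
#' @param contig_lengths Named numeric contig lengths.
#' @param min_len,max_len Length-filter bounds (see
#'   [score_bes_hits()]).
#' @return Data.frame of assignments (one row per assigned BES) with
#'   the query's `clone_id`, `end` and `source` joined on.
#' @export
assign_bes <- function(bes_queries, hits, contig_lengths,
                       min_len = 120, max_len = 1000) {
  rows <- lapply(seq_len(nrow(bes_queries)), function(i) {
    q <- bes_queries[i, ]
    h <- hits[hits$query_id == q$bes_id, , drop = FALSE]
    a <- score_bes_hits(h, contig_lengths, nchar(q$sequence),
                        min_len = min_len, max_len = max_len,
                        length_exempt = identical(q$source, "vector_end_proxy"))
    if (is.null(a)) return(NULL)
    a$clone_id <- q$clone_id
    a$end <- q$end
    a$source <- q$source
    a
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(bes_id = character(0), contig_id = character(0),
                      subject_start = integer(0), subject_end = integer(0),
                      strand = character(0), d_s = numeric(0), score = numeric(0),
                      competing_hits = integer(0), clone_id = character(0),
                      end = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Deconvolute a pooled assembly into clones
#'
#' Maps contigs to clones through BES assignments. A clone is fully
#' anchored when both its forward and reverse Sanger BES assign.
#' Contigs claimed by BES of two different clones are flagged as
#' conflicts and never silently resolved (a conflict signals clone
#' overlap or misassembly). If exactly one clone of the pool has no
#' Sanger BES, contigs carrying vector-end proxy assignments and
#' unclaimed by any other clone are attributed to it (anchored via
#' proxy when both proxy ends assign).
#'
#' @param assignments Output of [assign_bes()].
#' @param bes_queries The full BES query table of the pool.
#' @param pool_clone_ids Character vector: clone ids of the pool.
#' @param contig_ids All contig ids of the pooled assembly.
#' @return Object of class `deconvolution_report`: list with
#'   `contig_map` (data.frame contig_id/clone_id/via),
#'   `clone_summary` (per clone: n_contigs, anchored, via),
#'   `conflicts` (data.frame contig_id/clones), and `unassigned`
#'   (contig ids claimed by no clone).
#' @export
deconvolute_pool <- function(assignments, bes_queries, pool_clone_ids,
                             contig_ids) {
  sanger <- assignments[assignments$source == "sanger_bes", , drop = FALSE]
  proxy <- assignments[assignments$source == "vector_end_proxy", , drop = FALSE]

  # contig -> set of claiming clones (sanger only)
  claims <- unique(sanger[, c("contig_id", "clone_id")])
  claim_split <- split(claims$clone_id, claims$contig_id)
  conflict_ids <- names(claim_split)[lengths(claim_split) > 1]
  conflicts <- data.frame(
    contig_id = conflict_ids,
    clones = vapply(claim_split[conflict_ids],
                    function(x) paste(sort(x), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  clean <- claims[!(claims$contig_id %in% conflict_ids), , drop = FALSE]
  contig_map <- data.frame(contig_id = clean$contig_id,
                           clone_id = clean$clone_id,
                           via = "sanger_bes", stringsAsFactors = FALSE)

  # proxy attribution for a unique BES-less clone
  has_bes <- unique(bes_queries$clone_id[bes_queries$source == "sanger_bes"])
  no_bes <- setdiff(pool_clone_ids, has_bes)
  proxy_anchored <- FALSE
  if (length(no_bes) == 1 && nrow(proxy) > 0) {
    free <- setdiff(unique(proxy$contig_id),
                    c(contig_map$contig_id, conflict_ids))
    if (length(free) > 0) {
      contig_map <- rbind(contig_map, data.frame(
        contig_id = free, clone_id = no_bes, via = "vector_end_proxy",
        stringsAsFactors = FALSE))
      proxy_anchored <- all(c("forward", "reverse") %in%
                              proxy$end[proxy$contig_id %in% free])
    }
  }

  clone_summary <- do.call(rbind, lapply(pool_clone_ids, function(cl) {
    ends <- sanger$end[sanger$clone_id == cl]
    anchored_sanger <- all(c("forward", "reverse") %in% ends)
    via <- if (cl %in% has_bes) "sanger_bes" else "vector_end_proxy"
    anchored <- if (via == "sanger_bes") anchored_sanger else proxy_anchored
    data.frame(clone_id = cl,
               n_contigs = sum(contig_map$clone_id == cl),
               anchored = anchored,
               via = via,
               stringsAsFactors = FALSE)
  }))
  unassigned <- setdiff(contig_ids, c(contig_map$contig_id, conflict_ids))
  structure(list(contig_map = contig_map,
                 clone_summary = clone_summary,
                 conflicts = conflicts,
                 unassigned = unassigned),
            class = "deconvolution_report")
}

#' @export
print.deconvolution_report <- function(x, ...) {
  cat("Pool deconvolution report\n")
  cat(sprintf("  clones       : %d (%d anchored)\n",
              nrow(x$clone_summary), sum(x$clone_summary$anchored)))
  cat(sprintf("  contigs mapped: %d\n", nrow(x$contig_map)))
  cat(sprintf("  conflicts    : %d\n", nrow(x$conflicts)))
  cat(sprintf("  unassigned   : %d\n", length(x$unassigned)))
  invisible(x)
}

#' Pair pooled-assembly contigs to singleton assemblies
#'
#' Each contig of a pooled assembly is paired to the singleton (single
#' clone) assembly accumulating the greatest summed bit score over its
#' hits; the aligned fraction of the contig (union of query intervals)
#' is reported. Contigs with aligned fraction below `min_aligned_frac`
#' are flagged unpaired; contigs whose runner-up assembly reaches
#' `shared_ratio` of the best score are flagged shared.
#'
#' @param hits Hit data.frame with pool contigs as queries and
#'   singleton contigs as subjects.
#' @param pool_contig_lengths Named numeric: pool contig id -> length.
#' @param singleton_of Named character: singleton contig id ->
#'   singleton assembly (clone) id.
#' @param min_aligned_frac Minimum aligned fraction to call a pairing.
#' @param shared_ratio Runner-up / best summed-score ratio above which
#'   a contig is flagged shared.
#' @return Data.frame `(pool_contig, paired_assembly, summed_bit_score,
#'   aligned_frac, status)` with `status` in paired/shared/unpaired.
#' @export
pair_pool_to_singletons <- function(hits, pool_contig_lengths, singleton_of,
                                    min_aligned_frac = 0.5,
                                    shared_ratio = 0.5) {
  out <- lapply(names(pool_contig_lengths), function(qc) {
    h <- hits[hits$query_id == qc, , drop = FALSE]
    if (nrow(h) == 0) {
      return(data.frame(pool_contig = qc, paired_assembly = NA_character_,
                        summed_bit_score = 0, aligned_frac = 0,
                        status = "unpaired", stringsAsFactors = FALSE))
    }
    unknown <- setdiff(unique(h$subject_id), names(singleton_of))
    if (length(unknown) > 0) {
      stop("hits reference contigs with no singleton assembly: ",
           paste(unknown, collapse = ", "))
    }
    asm <- singleton_of[h$subject_id]
    scores <- tapply(h$bit_score, asm, sum)
    best <- names(scores)[which.max(scores)]
    best_score <- max(scores)
    second <- if (length(scores) > 1) max(scores[names(scores) != best]) else 0
    hb <- h[asm == best, , drop = FALSE]
    cov <- IRanges::reduce(IRanges::IRanges(hb$query_start + 1L, hb$query_end))
    frac <- sum(IRanges::width(cov)) / pool_contig_lengths[[qc]]
    status <- if (frac < min_aligned_frac) {
      "unpaired"
    } else if (second >= shared_ratio * best_score) {
      "shared"
    } else {
      "paired"
    }
    data.frame(pool_contig = qc,
               paired_assembly = if (status == "unpaired") NA_character_ else best,
               summed_bit_score = unname(best_score),
               aligned_frac = unname(frac),
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write BES assignments as TSV
#'
#' @param assignments Output of [assign_bes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
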