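#' Read a clone metadata table
#'
#' @param path TSV with columns `clone_id`, `fpc_contig`, `position`,
#'   `fpc_size_kb` (physical-map contig membership, ordering position
#'   within it, and the fingerprint-derived size estimate).
#' @return The data.frame.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) stop("clone table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone_id", "fpc_contig", "position", "fpc_size_kb")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("clone table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$clone_id)) stop("duplicate clone ids in clone table")
  df
}

#' Overlap edges from physical-map adjacency
#'
#' Minimal-tiling-path clones that are consecutive (by `position`)
#' within the same physical-map contig overlap by construction; each
#' consecutive pair becomes an overlap edge.
#'
#' @param clone_table Data.frame as from [read_clone_table()].
#' @return Data.frame `(a, b)` of unordered overlap edges.
#' @export
fpc_overlap_edges <- function(clone_table) {
  parts <- split(clone_table, clone_table$fpc_contig)
  edges <- lapply(parts, function(p) {
    p <- p[order(p$position), ]
    n <- nrow(p)
    if (n < 2) return(NULL)
    data.frame(a = p$clone_id[-n], b = p$clone_id[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, edges)
  if (is.null(out)) {
    out <- data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Partition clones into pools of non-overlapping clones
#'
#' Greedy randomised assignment: clones are shuffled and each is
#' placed in the first open pool containing no overlapping clone;
#' failed attempts restart with a fresh shuffle (up to
#' `max_restarts`). When the clone count is not divisible by
#' `pool_size` the remainder forms a smaller final pool (with a
#' warning). If no valid partition is found, the error names the
#' largest clique of mutually overlapping clones, which is the usual
#' obstruction.
#'
#' @param clone_ids Character vector of clone ids.
#' @param overlap_edges Data.frame `(a, b)` of overlap edges (may be
#'   empty or `NULL`).
#' @param pool_size Clones per pool (default 4).
#' @param seed Integer seed; output is deterministic under it.
#' @param max_restarts Maximum shuffles before giving up.
#' @return Data.frame `(clone_id, pool_id, well)`; `well` is a
#'   row-major 96-well position for the pool index.
#' @export
design_pools <- function(clone_ids, overlap_edges = NULL, pool_size = 4,
                         seed = 1L, max_restarts = 1000L) {
  if (pool_size < 1) stop("pool_size must be >= 1")
  n <- length(clone_ids)
  if (n == 0) stop("no clones supplied")
  if (anyDuplicated(clone_ids)) stop("duplicate clone ids")
  if (is.null(overlap_edges)) {
    overlap_edges <- data.frame(a = character(0), b = character(0))
  }
  bad <- setdiff(c(overlap_edges$a, overlap_edges$b), clone_ids)
  if (length(bad) > 0) stop("overlap edges name unknown clone(s): ",
                            paste(unique(bad), collapse = ", "))
  if (any(overlap_edges$a == overlap_edges$b)) stop("self-overlap edge")
  if (n %% pool_size != 0) {
    warning("clone count ", n, " not divisible by pool size ", pool_size,
            "; the final pool will be smaller")
  }
  nb <- split(c(overlap_edges$b, overlap_edges$a),
              c(overlap_edges$a, overlap_edges$b))
  n_pools <- ceiling(n / pool_size)
  assignment <- with_seed(seed, {
    result <- NULL
    for (attempt in seq_len(max_restarts)) {
      ord <- sample(clone_ids)
      pools <- vector("list", n_pools)
      ok <- TRUE
      for (cl in ord) {
        placed <- FALSE
        for (p in seq_len(n_pools)) {
          if (length(pools[[p]]) >= pool_size) next
          if (any(pools[[p]] %in% nb[[cl]])) next
          pools[[p]] <- c(pools[[p]], cl)
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) { result <- pools; break }
    }
    result
  })
  if (is.null(assignment)) {
    clique <- obstructing_clique(clone_ids, overlap_edges)
    stop("no valid pooling found after ", max_restarts,
         " restarts; obstructing clique: ", paste(clique, collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_along(assignment), function(p) {
    data.frame(clone_id = assignment[[p]],
               pool_id = sprintf("pool%03d", p),
               well = well_label(p),
               stringsAsFactors = FALSE)
  }))
  out[order(match(out$clone_id, clone_ids)), , drop = FALSE]
}

# Row-major 96-well label for a pool index (plates beyond the first
# are prefixed).
well_label <- function(i) {
  plate <- (i - 1L) %/% 96L
  pos <- (i - 1L) %% 96L
  lab <- sprintf("%s%02d", LETTERS[pos %/% 12L + 1L], pos %% 12L + 1L)
  if (plate > 0) lab <- sprintf("P%d:%s", plate + 1L, lab)
  lab
}

# Largest clique of the overlap graph, the canonical obstruction to a
# pooling.
obstructing_clique <- function(clone_ids, overlap_edges) {
  g <- igraph::graph_from_data_frame(overlap_edges, directed = FALSE,
                                     vertices = clone_ids)
  cl <- igraph::largest_cliques(g)
  if (length(cl) == 0) return(character(0))
  sort(names(cl[[1]]))
}

#' Per-lane coverage from the pooling arithmetic
#'
#' @param lane_bases Bases per sequencing lane (default 40 Gbp, an
#'   Illumina HiSeq 2000 lane).
#' @param n_bacs BACs multiplexed in the lane (default 384: 96 pools
#'   of four).
#' @param mean_bac_length Mean BAC insert length (bp, default 120 kb).
#' @return Expected per-BAC coverage, x-fold.
#' @export
expected_lane_coverage <- function(lane_bases = 40e9, n_bacs = 384,
                                   mean_bac_length = 120000) {
  if (lane_bases <= 0 || n_bacs <= 0 || mean_bac_length <= 0) {
    stop("all arguments must be positive")
  }
  lane_bases / (n_bacs * mean_bac_length)
}

#' Paired t test of assembly sizes against physical-map size estimates
#'
#' Classical paired t on the per-pool differences `assembly - fpc`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom
#' and a two-sided p value.
#'
#' @param assembly_sizes,fpc_sizes Equal-length numeric vectors
#'   (length >= 2) of per-pool sizes in the same unit.
#' @return Object of class `size_comparison`: list with `t`, `df`,
#'   `p_value`, `mean_difference`, `n`.
#' @export
compare_sizes_paired_t <- function(assembly_sizes, fpc_sizes) {
  if (length(assembly_sizes) != length(fpc_sizes)) {
    stop("size vectors must have equal length")
  }
  n <- length(assembly_sizes)
  if (n < 2) stop("need at least 2 pools")
  d <- assembly_sizes - fpc_sizes
  if (stats::sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(assembly_sizes, fpc_sizes, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(t = t_stat, df = n - 1L, p_value = p,
                 mean_difference = mean(d), n = n),
            class = "size_comparison")
}

#' @export
print.size_comparison <- function(x, ...) {
  cat(sprintf("Paired t test (assembly vs FPC sizes): t = %.3f, df = %d, p = %.4f\n",
              x$t, x$df, x$p_value))
  invisible(x)
}
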