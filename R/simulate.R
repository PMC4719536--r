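#' Simulation configuration for synthetic BAC pools
#'
#' Collects the library parameters used by the read simulators. The
#' defaults reproduce the sequencing regime the package targets:
#' 150 bp paired-end reads at a ~500 bp insert, mate pairs at 6-10 kb,
#' contamination near the middle of the observed per-pool ranges
#' (E. coli 10-28 %, vector 4-5 %, clonal duplicates 0.4-0.8 % of
#' pairs), and a mate-pair library that is ~99 % correctly outward
#' oriented (RF) with a small shadow (FR) and chimeric (FF/RR)
#' fraction.
#'
#' @param seed Integer seed controlling all randomness downstream.
#' @param read_length Read length in bp for PE and MP reads.
#' @param pe_insert_mean,pe_insert_sd Paired-end insert size (bp),
#'   truncated normal.
#' @param mp_insert_min,mp_insert_max Mate-pair insert size range (bp),
#'   uniform.
#' @param frac_ecoli,frac_vector,frac_clonal Fractions of emitted pairs
#'   that are E. coli contamination, vector contamination, and clonal
#'   duplicates. Each in \[0,1\] and jointly < 1.
#' @param mp_orientation_mix Length-3 numeric `(rf, fr, ff_rr)` summing
#'   to 1: the mate-pair orientation composition.
#' @param bes_length BAC-end (Sanger) read length in bp.
#' @param bes_error_rate Per-base substitution rate applied to BES.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       read_length = 150L,
                       pe_insert_mean = 500,
                       pe_insert_sd = 50,
                       mp_insert_min = 6000L,
                       mp_insert_max = 10000L,
                       frac_ecoli = 0.13,
                       frac_vector = 0.04,
                       frac_clonal = 0.006,
                       mp_orientation_mix = c(rf = 0.99, fr = 0.003, ff_rr = 0.007),
                       bes_length = 600L,
                       bes_error_rate = 0.001) {
  fr <- c(frac_ecoli, frac_vector, frac_clonal)
  if (any(fr < 0 | fr > 1)) stop("contamination fractions must each lie in [0,1]")
  if (sum(fr) >= 1) stop("contamination fractions must jointly be < 1")
  if (length(mp_orientation_mix) != 3) stop("mp_orientation_mix must have 3 components (rf, fr, ff_rr)")
  if (abs(sum(mp_orientation_mix) - 1) > 1e-9) stop("mp_orientation_mix must sum to 1")
  if (any(mp_orientation_mix < 0)) stop("mp_orientation_mix components must be non-negative")
  if (mp_insert_min > mp_insert_max) stop("mp_insert_min must be <= mp_insert_max")
  if (read_length < 1) stop("read_length must be positive")
  structure(list(
    seed = as.integer(seed),
    read_length = as.integer(read_length),
    pe_insert_mean = pe_insert_mean,
    pe_insert_sd = pe_insert_sd,
    mp_insert_min = as.integer(mp_insert_min),
    mp_insert_max = as.integer(mp_insert_max),
    frac_ecoli = frac_ecoli,
    frac_vector = frac_vector,
    frac_clonal = frac_clonal,
    mp_orientation_mix = stats::setNames(as.numeric(mp_orientation_mix),
                                         c("rf", "fr", "ff_rr")),
    bes_length = as.integer(bes_length),
    bes_error_rate = bes_error_rate
  ), class = "sim_config")
}

#' Simulate one BAC clone insert with known repeat structure
#'
#' The insert is a mosaic of unique random sequence and copies of a
#' small per-clone library of repeat units; each copy carries 1 %
#' per-base divergence. Repeat copies occupy `repeat_fraction` of the
#' insert to within 2 %. BAC-end sequences (BES) are taken from the
#' terminal `bes_length` bases: the forward BES is a prefix of the
#' insert, the reverse BES the reverse complement of a suffix; both
#' carry Sanger-like substitution errors.
#'
#' @param clone_id Clone identifier.
#' @param length Insert length in bp (typical BAC inserts: 100-130 kb).
#' @param repeat_fraction Target fraction of repeat-derived bases, in
#'   \[0, 0.95\].
#' @param repeat_unit_length Length of each repeat unit (bp).
#' @param n_repeat_units Number of distinct repeat units in the
#'   per-clone library.
#' @param bes_length BES length (bp).
#' @param bes_error_rate Per-base BES substitution rate.
#' @param seed Integer seed; identical arguments and seed give a
#'   byte-identical clone.
#' @return An object of class `sim_clone`: list with `clone_id`,
#'   `insert`, `repeat_fraction` (realised), `repeat_mask` (logical per
#'   base), `bes_forward`, `bes_reverse`.
#' @export
simulate_clone <- function(clone_id = "clone1",
                           length = 120000L,
                           repeat_fraction = 0.8,
                           repeat_unit_length = 1000L,
                           n_repeat_units = 5L,
                           bes_length = 600L,
                           bes_error_rate = 0.001,
                           seed = 1L) {
  length <- as.integer(length)
  if (repeat_fraction < 0 || repeat_fraction > 0.95) {
    stop("repeat_fraction must lie in [0, 0.95]")
  }
  if (length < 10L * repeat_unit_length) {
    stop("insert length must be at least 10 x repeat_unit_length")
  }
  if (length < 2L * bes_length) stop("insert too short for BES extraction")
  with_seed(seed, {
    repeat_bases <- round(repeat_fraction * length)
    if (repeat_bases > length) {
      stop("infeasible repeat_fraction / repeat_unit_length combination")
    }
    n_full <- repeat_bases %/% repeat_unit_length
    tail_len <- repeat_bases %% repeat_unit_length
    copy_lens <- c(rep(repeat_unit_length, n_full),
                   if (tail_len > 0) tail_len)
    n_copies <- length(copy_lens)
    realised <- repeat_bases / length
    units <- replicate(n_repeat_units, random_dna(repeat_unit_length))
    unique_total <- length - repeat_bases
    # split the unique sequence into n_copies + 1 chunks, repeats between
    n_chunks <- n_copies + 1L
    cuts <- if (n_chunks > 1L) sort(sample.int(unique_total + 1L, n_chunks - 1L, replace = TRUE) - 1L) else integer(0)
    chunk_len <- diff(c(0L, cuts, unique_total))
    segs <- character(0)
    mask <- logical(0)
    for (i in seq_len(n_chunks)) {
      u <- random_dna(chunk_len[i])
      segs <- c(segs, u)
      mask <- c(mask, rep(FALSE, chunk_len[i]))
      if (i <= n_copies) {
        rep_copy <- mutate_dna(units[[sample.int(n_repeat_units, 1L)]], 0.01)
        rep_copy <- substr(rep_copy, 1L, copy_lens[i])
        segs <- c(segs, rep_copy)
        mask <- c(mask, rep(TRUE, copy_lens[i]))
      }
    }
    insert <- paste(segs, collapse = "")
    stopifnot(nchar(insert) == length)
    bes_f <- mutate_dna(substr(insert, 1L, bes_length), bes_error_rate)
    bes_r <- mutate_dna(revcomp(substr(insert, length - bes_length + 1L, length)),
                        bes_error_rate)
    structure(list(
      clone_id = clone_id,
      insert = insert,
      repeat_fraction = realised,
      repeat_mask = mask,
      bes_forward = bes_f,
      bes_reverse = bes_r
    ), class = "sim_clone")
  })
}

#' Assemble simulated clones into a pool
#'
#' @param pool_id Pool identifier.
#' @param clones List of [simulate_clone()] objects (typically 4
#'   non-overlapping clones per pool).
#' @return An object of class `sim_pool`.
#' @export
simulate_pool <- function(pool_id, clones) {
  if (length(clones) == 0) stop("a pool needs at least one clone")
  ids <- vapply(clones, function(cl) cl$clone_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate clone ids in pool")
  structure(list(pool_id = pool_id, clones = clones), class = "sim_pool")
}

#' Generate mock contaminant references
#'
#' Produces a random "ecoli" genome fragment and "vector" backbone that
#' provably share no read-length substring with the supplied inserts:
#' sharing a window of `read_length` >= `check_k` bases implies sharing
#' a `check_k`-mer, and the generator verifies the `check_k`-mer sets
#' are disjoint (regenerating on the astronomically rare collision).
#' This makes contaminant-filter recall and precision exactly
#' measurable on simulated data.
#'
#' @param inserts Character vector of insert sequences to stay disjoint
#'   from (may be empty).
#' @param read_length Screening word size the filter will use.
#' @param ecoli_length,vector_length Mock reference lengths (bp).
#' @param check_k k-mer size used for the disjointness census; must be
#'   <= `read_length`.
#' @param seed Integer seed.
#' @return Named character vector with elements `ecoli` and `vector`.
#' @export
make_mock_contaminants <- function(inserts = character(0),
                                   read_length = 150L,
                                   ecoli_length = 50000L,
                                   vector_length = 7500L,
                                   check_k = 31L,
                                   seed = 1L) {
  if (check_k > read_length) stop("check_k must be <= read_length")
  with_seed(seed, {
    insert_kmers <- NULL
    if (length(inserts) > 0) {
      insert_kmers <- unique(unlist(lapply(inserts, seq_kmers, k = check_k)))
      insert_kmers <- unique(c(insert_kmers, revcomp(insert_kmers)))
    }
    for (attempt in 1:10) {
      refs <- c(ecoli = random_dna(ecoli_length), vector = random_dna(vector_length))
      if (is.null(insert_kmers)) return(refs)
      contam_kmers <- unique(unlist(lapply(refs, seq_kmers, k = check_k)))
      if (!any(contam_kmers %in% insert_kmers)) return(refs)
    }
    stop("could not generate contaminants disjoint from inserts")
  })
}

# Draw n PE pairs from one reference sequence. Fragment starts uniform,
# insert length truncated-normal clipped to [read_length, ref length].
# Returns read1 = forward prefix of the fragment, read2 = reverse
# complement of its suffix; with probability 1/2 the fragment is read
# from the other strand, which swaps the mates.
draw_pe_pairs <- function(ref, n, cfg) {
  if (n == 0L) {
    return(data.frame(read1 = character(0), read2 = character(0),
                      stringsAsFactors = FALSE))
  }
  L <- nchar(ref)
  rl <- cfg$read_length
  ins <- round(stats::rnorm(n, cfg$pe_insert_mean, cfg$pe_insert_sd))
  ins <- pmin(pmax(ins, rl), L)
  s <- floor(stats::runif(n, 0, L - ins + 1))
  r1 <- substr_many(ref, s, rl)
  r2 <- revcomp(substr_many(ref, s + ins - rl, rl))
  flip <- stats::runif(n) < 0.5
  data.frame(
    read1 = ifelse(flip, r2, r1),
    read2 = ifelse(flip, r1, r2),
    stringsAsFactors = FALSE
  )
}

#' Simulate paired-end reads for a BAC pool with ground truth
#'
#' Emits `ceiling(target_coverage * total_insert_length / (2 *
#' read_length))` insert-derived pairs, then adds E. coli, vector and
#' clonal pairs so that each class's share of the final total matches
#' the configured fractions. Clonal pairs are byte-identical copies of
#' already-emitted pairs. Every pair carries a truth label.
#'
#' @param pool A [simulate_pool()] object.
#' @param target_coverage Per-pool sequence coverage (x-fold over the
#'   summed insert length).
#' @param cfg A [sim_config()].
#' @param contaminants Optional named character vector (`ecoli`,
#'   `vector`) as from [make_mock_contaminants()]; generated (disjoint
#'   from the pool inserts) when `NULL`.
#' @return List with `pairs` (data.frame: `pair_id`, `read1`, `read2`,
#'   `truth` in insert/ecoli/vector/clonal, `clone_id`) and
#'   `contaminants` (the references used).
#' @export
simulate_pool_reads <- function(pool, target_coverage, cfg = sim_config(),
                                contaminants = NULL) {
  if (!inherits(pool, "sim_pool")) stop("pool must be a sim_pool")
  if (target_coverage <= 0) stop("target_coverage must be positive")
  inserts <- vapply(pool$clones, function(cl) cl$insert, character(1))
  clone_ids <- vapply(pool$clones, function(cl) cl$clone_id, character(1))
  lens <- nchar(inserts)
  with_seed(cfg$seed, {
    if (is.null(contaminants)) {
      contaminants <- make_mock_contaminants(
        inserts, read_length = cfg$read_length,
        seed = sample.int(.Machine$integer.max, 1L)
      )
    }
    n_insert <- ceiling(target_coverage * sum(lens) / (2 * cfg$read_length))
    f_e <- cfg$frac_ecoli; f_v <- cfg$frac_vector; f_c <- cfg$frac_clonal
    total <- n_insert / (1 - f_e - f_v - f_c)
    n_ecoli <- round(f_e * total)
    n_vector <- round(f_v * total)
    n_clonal <- round(f_c * total)

    which_clone <- sample.int(length(inserts), n_insert, replace = TRUE,
                              prob = lens / sum(lens))
    ins_pairs <- do.call(rbind, lapply(seq_along(inserts), function(i) {
      k <- sum(which_clone == i)
      p <- draw_pe_pairs(inserts[i], k, cfg)
      if (k > 0) {
        p$truth <- "insert"
        p$clone_id <- clone_ids[i]
      } else {
        p$truth <- character(0)
        p$clone_id <- character(0)
      }
      p
    }))
    ec_pairs <- draw_pe_pairs(contaminants[["ecoli"]], n_ecoli, cfg)
    if (n_ecoli > 0) { ec_pairs$truth <- "ecoli"; ec_pairs$clone_id <- NA_character_ }
    vc_pairs <- draw_pe_pairs(contaminants[["vector"]], n_vector, cfg)
    if (n_vector > 0) { vc_pairs$truth <- "vector"; vc_pairs$clone_id <- NA_character_ }
    base <- rbind(ins_pairs,
                  if (n_ecoli > 0) ec_pairs,
                  if (n_vector > 0) vc_pairs)
    if (n_clonal > 0) {
      src <- sample.int(nrow(base), n_clonal, replace = TRUE)
      dup <- base[src, , drop = FALSE]
      dup$truth <- "clonal"
      base <- rbind(base, dup)
    }
    base$pair_id <- sprintf("%s_p%07d", pool$pool_id, seq_len(nrow(base)))
    rownames(base) <- NULL
    list(
      pairs = base[, c("pair_id", "read1", "read2", "truth", "clone_id")],
      contaminants = contaminants
    )
  })
}

#' Simulate mate-pair reads with truth orientation
#'
#' Each pair is drawn from a fragment whose length is uniform on
#' `[mp_insert_min, mp_insert_max]`. The orientation class is sampled
#' from `cfg$mp_orientation_mix`: RF pairs are emitted outward-facing
#' (leftmost mate on the minus strand, rightmost on plus), FR pairs
#' inward-facing, and FF/RR pairs same-facing. The construction
#' coordinates of both mates on the reference are recorded so
#' orientation calls can be checked against truth.
#'
#' @param reference A single reference sequence (character or
#'   DNAString-like) longer than `mp_insert_max + 2 * read_length`.
#' @param n_pairs Number of pairs to draw (0 gives an empty table).
#' @param cfg A [sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @param reference_id Contig id recorded in the output.
#' @return Data.frame with columns `pair_id`, `read1`, `read2`,
#'   `contig1`, `start1`, `end1`, `strand1`, `contig2`, `start2`,
#'   `end2`, `strand2`, `truth_class` (RF/FR/FF_RR), `insert_size`.
#' @export
simulate_mate_pairs <- function(reference, n_pairs, cfg = sim_config(),
                                seed = cfg$seed, reference_id = "ref") {
  ref <- as.character(reference)[1]
  L <- nchar(ref)
  rl <- cfg$read_length
  if (L <= cfg$mp_insert_max + 2L * rl) {
    stop("reference too short for the configured mate-pair insert range")
  }
  cols <- c("pair_id", "read1", "read2", "contig1", "start1", "end1", "strand1",
            "contig2", "start2", "end2", "strand2", "truth_class", "insert_size")
  if (n_pairs == 0L) {
    out <- data.frame(pair_id = character(0), read1 = character(0),
                      read2 = character(0), contig1 = character(0),
                      start1 = integer(0), end1 = integer(0), strand1 = character(0),
                      contig2 = character(0), start2 = integer(0), end2 = integer(0),
                      strand2 = character(0), truth_class = character(0),
                      insert_size = integer(0), stringsAsFactors = FALSE)
    return(out[, cols])
  }
  with_seed(seed, {
    ins <- floor(stats::runif(n_pairs, cfg$mp_insert_min, cfg$mp_insert_max + 1))
    s <- floor(stats::runif(n_pairs, 0, L - ins + 1))
    e <- s + ins
    cls <- sample(c("RF", "FR", "FF_RR"), n_pairs, replace = TRUE,
                  prob = cfg$mp_orientation_mix)
    left_fwd <- substr_many(ref, s, rl)
    right_fwd <- substr_many(ref, e - rl, rl)
    # strand of leftmost / rightmost mate per class
    strand_left <- ifelse(cls == "RF", "-",
                          ifelse(cls == "FR", "+",
                                 ifelse(stats::runif(n_pairs) < 0.5, "+", "-")))
    strand_right <- ifelse(cls == "FF_RR", strand_left,
                           ifelse(strand_left == "-", "+", "-"))
    seq_left <- ifelse(strand_left == "-", revcomp(left_fwd), left_fwd)
    seq_right <- ifelse(strand_right == "-", revcomp(right_fwd), right_fwd)
    # assign mate labels 1/2 at random so classification cannot rely on them
    left_is_1 <- stats::runif(n_pairs) < 0.5
    out <- data.frame(
      pair_id = sprintf("mp%07d", seq_len(n_pairs)),
      read1 = ifelse(left_is_1, seq_left, seq_right),
      read2 = ifelse(left_is_1, seq_right, seq_left),
      contig1 = reference_id,
      start1 = ifelse(left_is_1, s, e - rl),
      end1 = ifelse(left_is_1, s + rl, e),
      strand1 = ifelse(left_is_1, strand_left, strand_right),
      contig2 = reference_id,
      start2 = ifelse(left_is_1, e - rl, s),
      end2 = ifelse(left_is_1, e, s + rl),
      strand2 = ifelse(left_is_1, strand_right, strand_left),
      truth_class = cls,
      insert_size = as.integer(ins),
      stringsAsFactors = FALSE
    )
    out[, cols]
  })
}

#' Write simulator truth labels to a TSV
#'
#' @param pairs Data.frame carrying at least `pair_id` and `truth`
#'   (and optionally `clone_id`, `truth_class`, `insert_size`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(pairs, path) {
  keep <- intersect(c("pair_id", "truth", "clone_id", "truth_class", "insert_size"),
                    names(pairs))
  utils::write.table(pairs[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
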