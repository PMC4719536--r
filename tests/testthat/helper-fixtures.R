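# Shared fixtures: a toy k-mer assembler, a mismatch-tolerant exact-seed
# hit generator, and converters from simulator output to the mapped-pair
# layout. These stand in for the external assembler / aligner in tests.

rc1 <- function(x) bacpool::revcomp(x)

seq_kmers_oracle <- function(seq, k) {
  substring(seq, 1:(nchar(seq) - k + 1), k:nchar(seq))
}

all_kmers <- function(seqs, k) {
  rl <- nchar(seqs)
  stopifnot(length(unique(rl)) == 1)
  rl <- rl[1]
  if (rl < k) return(character(0))
  unlist(lapply(seq_len(rl - k + 1L), function(i) substr(seqs, i, i + k - 1L)))
}

# Toy assembler: counts canonical k-mers across all reads and reports
# the length spanned by k-mers seen at least `min_count` times. On a
# repeat-free reference this rises with coverage and saturates at the
# reference length, which is all the saturation analysis needs.
toy_assembler <- function(k = 31L, min_count = 2L) {
  function(pairs) {
    reads <- c(pairs$read1, pairs$read2)
    km <- all_kmers(reads, k)
    canon <- pmin(km, rc1(km))
    counts <- rle(sort(canon))
    good <- sum(counts$lengths >= min_count)
    if (good == 0) 0 else good + k - 1L
  }
}

count_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Minimal hit generator (aligner stand-in): finds occurrences of each
# query in each contig on both strands allowing up to `max_mismatch`
# substitutions, and emits hits in the internal 0-based convention with
# a mock bit score of 2 * (len - 3 * mismatches).
make_query_hits <- function(queries, contigs, max_mismatch = 8L) {
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    qseq <- queries$sequence[qi]
    qid <- queries$bes_id[qi]
    qlen <- nchar(qseq)
    for (ci in seq_along(contigs)) {
      subj <- Biostrings::DNAString(contigs[[ci]])
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") qseq else rc1(qseq)
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m) == 0) next
        starts <- Biostrings::start(m)
        for (j in seq_along(starts)) {
          hit_seq <- as.character(m[[j]])
          mm <- count_mismatches(hit_seq, pat)
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = qid, subject_id = names(contigs)[ci],
            percent_identity = 100 * (qlen - mm) / qlen,
            aligned_length = qlen, mismatches = mm, gap_opens = 0L,
            query_start = 0L, query_end = qlen,
            subject_start = starts[j] - 1L,
            subject_end = starts[j] - 1L + qlen,
            strand = strand, evalue = 0,
            bit_score = 2 * (qlen - 3 * mm),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(bacpool::read_blast_tabular(tempfile())[0, ])
  }
  do.call(rbind, rows)
}

# Simulator MP output -> mapped-pair layout consumed by the QC ops.
mp_to_mapped <- function(mp, read_length) {
  data.frame(
    pair_id = mp$pair_id,
    contig1 = mp$contig1, start1 = mp$start1, end1 = mp$end1,
    strand1 = mp$strand1, identity1 = 100, aligned1 = read_length,
    read_len1 = read_length, hit_count1 = 1L,
    contig2 = mp$contig2, start2 = mp$start2, end2 = mp$end2,
    strand2 = mp$strand2, identity2 = 100, aligned2 = read_length,
    read_len2 = read_length, hit_count2 = 1L,
    stringsAsFactors = FALSE
  )
}

# Re-express MP pairs simulated on a whole reference as mappings onto
# the two contigs obtained by deleting [break_at, break_at + gap) from
# it; pairs with a mate crossing or inside the gap are dropped.
split_reference_links <- function(mp, break_at, gap, ref_length) {
  in_c1 <- function(s, e) e <= break_at
  in_c2 <- function(s, e) s >= break_at + gap
  keep <- (in_c1(mp$start1, mp$end1) | in_c2(mp$start1, mp$end1)) &
    (in_c1(mp$start2, mp$end2) | in_c2(mp$start2, mp$end2))
  mp <- mp[keep, , drop = FALSE]
  remap <- function(s, e) {
    on2 <- s >= break_at + gap
    list(contig = ifelse(on2, "c2", "c1"),
         start = ifelse(on2, s - break_at - gap, s),
         end = ifelse(on2, e - break_at - gap, e))
  }
  m1 <- remap(mp$start1, mp$end1)
  m2 <- remap(mp$start2, mp$end2)
  data.frame(
    pair_id = mp$pair_id,
    contig_a = m1$contig, start_a = m1$start, end_a = m1$end,
    strand_a = mp$strand1,
    contig_b = m2$contig, start_b = m2$start, end_b = m2$end,
    strand_b = mp$strand2,
    stringsAsFactors = FALSE
  )
}
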