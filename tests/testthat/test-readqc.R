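test_that("exact index membership is strand-symmetric and exact", {
  idx <- build_exact_index(c(ref = "ACGTACGT"), w = 4)
  expect_true(index_member(idx, "ACGT"))
  expect_false(index_member(idx, "AAAA"))
  # "TACG" is the reverse complement of "CGTA", present on the forward strand
  expect_true(index_member(idx, "TACG"))
  # full enumeration oracle: membership of every 4-mer over both strands
  all4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1, paste,
                collapse = "")
  truth <- all4 %in% c(seq_kmers_oracle("ACGTACGT", 4),
                       seq_kmers_oracle(rc1("ACGTACGT"), 4))
  expect_equal(index_member(idx, all4), truth)

  expect_error(build_exact_index(c(r = "ACG"), w = 4), "shortest reference")
  # N-containing words are never indexed
  idxn <- build_exact_index(c(r = "ACGNACGT"), w = 4)
  expect_false(index_member(idxn, "ACGN"))
})

test_that("contaminant filtering is pair-atomic with vector precedence", {
  ecoli <- c(ecoli = "ACGTACGTACGTACGT")
  vect <- c(vector = "TTTTCCCCGGGGAAAA")
  e_idx <- build_exact_index(ecoli, 8)
  v_idx <- build_exact_index(vect, 8)
  pairs <- data.frame(
    pair_id = c("p1", "p2", "p3", "p4"),
    read1 = c("ACGTACGT",      # ecoli hit on read1
              "CATGCATG",      # clean
              "TTTTCCCC",      # vector hit on read1
              "ACGTACGT"),     # hits both references via the two mates
    read2 = c("CATGGTAC", "GTACCATG", "CATGGTAC", "CCCCGGGG"),
    stringsAsFactors = FALSE
  )
  res <- filter_contaminant_pairs(pairs, e_idx, v_idx)
  expect_equal(res$removed_class, c("ecoli", "kept", "vector", "vector"))
  expect_equal(res$kept$pair_id, "p2")
  expect_equal(res$input_pairs, 4)
  expect_equal(res$removed_vector_pairs + res$removed_ecoli_pairs +
                 nrow(res$kept), 4)
  # idempotence
  res2 <- filter_contaminant_pairs(res$kept, e_idx, v_idx)
  expect_equal(nrow(res2$kept), nrow(res$kept))
  # mismatched read length errors
  bad <- data.frame(pair_id = "x", read1 = "ACGT", read2 = "ACGT")
  expect_error(filter_contaminant_pairs(bad, e_idx, v_idx), "length 8")
})

test_that("clonal removal keeps the first representative", {
  pairs <- data.frame(
    pair_id = c("a", "b", "c", "d"),
    read1 = c("ACGT", "ACGT", "GGGG", "TTTT"),
    read2 = c("TTTT", "TTTT", "CCCC", "ACGT"),
    stringsAsFactors = FALSE
  )
  res <- remove_clonal_pairs(pairs)
  # d is a's fragment read from the other strand: (rc(TTTT), rc(ACGT)) = (AAAA, ACGT)?
  # no: rc("TTTT")="AAAA" != "ACGT", so d is distinct; only b duplicates a.
  expect_equal(res$clonal_pairs, 1)
  expect_equal(res$kept$pair_id, c("a", "c", "d"))

  # opposite-strand duplicate is caught: (r1, r2) vs (rc(r2), rc(r1))
  p2 <- data.frame(pair_id = c("x", "y"),
                   read1 = c("ACGG", "CCGT"), read2 = c("ACGT", "CCGT"),
                   stringsAsFactors = FALSE)
  # y = (rc("ACGT"), rc("ACGG")) = ("ACGT" -> "ACGT"?) construct explicitly:
  p2$read1[2] <- rc1(p2$read2[1])
  p2$read2[2] <- rc1(p2$read1[1])
  expect_equal(remove_clonal_pairs(p2)$clonal_pairs, 1)

  expect_equal(remove_clonal_pairs(pairs[0, ])$clonal_pairs, 0)
})

test_that("clonal percentage arithmetic matches the planted rate", {
  set.seed(1)
  base <- data.frame(
    pair_id = sprintf("p%04d", 1:994),
    read1 = replicate(994, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                                 collapse = "")),
    read2 = replicate(994, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                                 collapse = "")),
    stringsAsFactors = FALSE
  )
  dup <- base[1:6, ]
  dup$pair_id <- paste0(dup$pair_id, "_dup")
  pairs <- rbind(base, dup)
  res <- remove_clonal_pairs(pairs)
  expect_equal(res$clonal_pairs, 6)
  expect_equal(100 * res$clonal_pairs / nrow(pairs), 0.6)
})

test_that("coverage estimation reports integer folds per unit", {
  expect_equal(estimate_coverage(97320000, 1), 811)
  expect_equal(estimate_coverage(40e9, 384), 868)
  expect_equal(estimate_coverage(0, 1), 0)
  expect_error(estimate_coverage(100, 0), "positive")
})

test_that("QC on simulated pools: full recall, zero false removal, converging percentages", {
  cl <- simulate_clone("c1", length = 40000, repeat_fraction = 0.5, seed = 21)
  pool <- simulate_pool("pA", list(cl))
  cfg <- sim_config(seed = 22, read_length = 100, frac_ecoli = 0.12,
                    frac_vector = 0.05, frac_clonal = 0.006)
  sim <- simulate_pool_reads(pool, target_coverage = 60, cfg)
  pairs <- sim$pairs
  qc <- run_readqc(pairs, ecoli_ref = sim$contaminants["ecoli"],
                   vector_ref = sim$contaminants["vector"],
                   n_bacs = 1, unit_length = 40000)
  n <- nrow(pairs)
  n_ecoli <- sum(pairs$truth == "ecoli")
  n_vector <- sum(pairs$truth == "vector")
  # every planted contaminant pair removed (recall 100 %)...
  removed <- n - qc$kept_pairs
  expect_gte(qc$removed_ecoli_pairs + qc$removed_vector_pairs,
             n_ecoli + n_vector)
  # ...and no insert-labelled pair removed by the contaminant filter
  e_idx0 <- build_exact_index(sim$contaminants["ecoli"], 100)
  v_idx0 <- build_exact_index(sim$contaminants["vector"], 100)
  filt <- filter_contaminant_pairs(pairs, e_idx0, v_idx0)
  expect_equal(sum(filt$kept$truth %in% c("ecoli", "vector")), 0)
  expect_equal(sum(filt$kept$truth == "insert"), sum(pairs$truth == "insert"))
  kept_truth <- pairs$truth[pairs$pair_id %in% qc$kept$pair_id]
  expect_equal(sum(kept_truth %in% c("ecoli", "vector")), 0)
  # percentages converge to simulator fractions (3 sigma binomial)
  for (chk in list(c(qc$vector_pct / 100, 0.05),
                   c(qc$ecoli_pct / 100, 0.12))) {
    expect_lt(abs(chk[1] - chk[2]), 3 * sqrt(chk[2] * (1 - chk[2]) / n))
  }
  # pair-atomicity / accounting invariant
  expect_equal(qc$kept_pairs + qc$removed_vector_pairs +
                 qc$removed_ecoli_pairs + qc$removed_clonal_pairs, n)
  # no kept read is a member of either contaminant index
  e_idx <- build_exact_index(sim$contaminants["ecoli"], 100)
  v_idx <- build_exact_index(sim$contaminants["vector"], 100)
  expect_false(any(index_member(e_idx, qc$kept$read1) |
                     index_member(e_idx, qc$kept$read2) |
                     index_member(v_idx, qc$kept$read1) |
                     index_member(v_idx, qc$kept$read2)))
})
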