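mk_hit <- function(query, subject, sstart, send, bit, strand = "+") {
  data.frame(query_id = query, subject_id = subject,
             percent_identity = 100, aligned_length = send - sstart,
             mismatches = 0L, gap_opens = 0L, query_start = 0L,
             query_end = send - sstart, subject_start = sstart,
             subject_end = send, strand = strand, evalue = 0,
             bit_score = bit, stringsAsFactors = FALSE)
}

test_that("edge distance is the shortest distance to either contig end", {
  expect_equal(edge_distance(95000, 95500, 100000), 4500)
  expect_equal(edge_distance(0, 600, 100000), 0)
  expect_equal(edge_distance(400, 600, 1000), 400)
  expect_error(edge_distance(900, 1100, 1000), "outside")
})

test_that("BES scoring subtracts edge distance from bit score and filters by length", {
  lens <- c(ctg1 = 100000, ctg2 = 50000)
  a <- score_bes_hits(mk_hit("b1", "ctg1", 50, 650, 200), lens, bes_length = 600)
  expect_equal(a$score, 200 - 50)
  expect_equal(a$d_s, 50)

  # the higher S wins even against a higher bit score
  h <- rbind(mk_hit("b1", "ctg1", 10, 610, 180),   # S = 170
             mk_hit("b1", "ctg2", 60, 660, 200))   # S = 140
  best <- score_bes_hits(h, lens, bes_length = 600)
  expect_equal(best$contig_id, "ctg1")
  expect_equal(best$score, 170)

  # length filter: strict bounds 120 < len < max_len
  expect_null(score_bes_hits(mk_hit("b1", "ctg1", 0, 120, 100), lens,
                             bes_length = 120))
  expect_null(score_bes_hits(mk_hit("b1", "ctg1", 0, 1000, 100), lens,
                             bes_length = 1000))
  # proxies bypass the filter
  expect_false(is.null(score_bes_hits(mk_hit("v1", "ctg1", 0, 120, 100), lens,
                                      bes_length = 120, length_exempt = TRUE)))
  # unknown contig errors
  expect_error(score_bes_hits(mk_hit("b1", "nope", 0, 600, 100), lens,
                              bes_length = 600), "unknown contig")
})

test_that("ties break by bit score, then smaller d_s, then contig id", {
  lens <- c(a = 10000, b = 10000, c = 10000)
  # equal S, unequal bit score
  h <- rbind(mk_hit("q", "a", 100, 700, 150),  # S = 50
             mk_hit("q", "b", 50, 650, 100))   # S = 50
  expect_equal(score_bes_hits(h, lens, 600)$contig_id, "a")
  # equal S and bit score, unequal d_s is impossible (S = b - d_s), so
  # fully tied hits fall through to contig id
  h2 <- rbind(mk_hit("q", "c", 100, 700, 150),
              mk_hit("q", "a", 100, 700, 150))
  expect_equal(score_bes_hits(h2, lens, 600)$contig_id, "a")
})

test_that("a single hit is always assigned, and <=20-hit sets match brute force", {
  lens <- stats::setNames(rep(50000, 6), paste0("c", 1:6))
  single <- mk_hit("q", "c3", 40000, 40600, 12)  # terrible score, still assigned
  expect_equal(score_bes_hits(single, lens, 600)$contig_id, "c3")

  set.seed(7)
  for (rep in 1:25) {
    n <- sample(1:20, 1)
    s <- sample.int(49000, n)
    h <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_hit("q", sample(names(lens), 1), s[i], s[i] + 600,
             round(runif(1, 100, 1200), 1))
    }))
    got <- score_bes_hits(h, lens, 600)
    # exhaustive oracle over all hits
    S <- h$bit_score - pmin(h$subject_start, lens[h$subject_id] - h$subject_end)
    best <- which(S == max(S))
    if (length(best) > 1) {
      best <- best[order(-h$bit_score[best], h$subject_id[best])][1]
    }
    expect_equal(got$score, unname(max(S)))
    expect_equal(got$contig_id, h$subject_id[best])
  }
})

test_that("monotonicity: S increases in bit score, decreases in d_s", {
  lens <- c(x = 10000)
  s1 <- score_bes_hits(mk_hit("q", "x", 500, 1100, 100), lens, 600)$score
  s2 <- score_bes_hits(mk_hit("q", "x", 500, 1100, 150), lens, 600)$score
  expect_gt(s2, s1)
  s3 <- score_bes_hits(mk_hit("q", "x", 900, 1500, 100), lens, 600)$score
  expect_lt(s3, s1)
})

test_that("pool deconvolution anchors clones and reports conflicts", {
  # 4 clones, truth contigs = inserts, BES generated by the simulator
  clones <- lapply(1:4, function(i) {
    simulate_clone(paste0("cl", i), length = 15000, repeat_fraction = 0.3,
                   repeat_unit_length = 500, seed = 40 + i)
  })
  contigs <- stats::setNames(vapply(clones, `[[`, character(1), "insert"),
                             paste0("ctg", 1:4))
  lens <- stats::setNames(nchar(contigs), names(contigs))
  bq <- bes_queries_from_clones(clones)
  hits <- make_query_hits(bq, contigs, max_mismatch = 12)
  asn <- assign_bes(bq, hits, lens)
  rep <- deconvolute_pool(asn, bq, paste0("cl", 1:4), names(contigs))
  expect_equal(nrow(rep$conflicts), 0)
  expect_true(all(rep$clone_summary$anchored))
  # every contig mapped to its true clone
  truth <- stats::setNames(paste0("cl", 1:4), paste0("ctg", 1:4))
  expect_equal(nrow(rep$contig_map), 4)
  expect_equal(stats::setNames(rep$contig_map$clone_id, rep$contig_map$contig_id)[names(truth)],
               truth)

  # two clones' BES on one contig -> conflict, never silently resolved
  asn2 <- asn
  asn2$contig_id[asn2$clone_id == "cl2"] <- "ctg1"
  rep2 <- deconvolute_pool(asn2, bq, paste0("cl", 1:4), names(contigs))
  expect_equal(rep2$conflicts$contig_id, "ctg1")
  expect_false("ctg1" %in% rep2$contig_map$contig_id)
})

test_that("a BES-less clone is anchored through vector-end proxies", {
  clones <- lapply(1:4, function(i) {
    simulate_clone(paste0("cl", i), length = 15000, repeat_fraction = 0.2,
                   repeat_unit_length = 500, seed = 50 + i)
  })
  # clone 2 ("clone B") has no BES; its insert is flanked by vector ends
  vec <- bacpool:::with_seed(99, bacpool:::random_dna(2000))
  insert2 <- clones[[2]]$insert
  contigs <- stats::setNames(vapply(clones, `[[`, character(1), "insert"),
                             paste0("ctg", 1:4))
  contigs["ctg2"] <- paste0(substr(vec, 2000 - 119, 2000), insert2,
                            substr(vec, 1, 120))
  lens <- stats::setNames(nchar(contigs), names(contigs))
  bq <- rbind(bes_queries_from_clones(clones[-2]),
              make_vector_end_proxies(vec))
  hits <- make_query_hits(bq, contigs, max_mismatch = 12)
  asn <- assign_bes(bq, hits, lens)
  rep <- deconvolute_pool(asn, bq, paste0("cl", 1:4), names(contigs))
  s2 <- rep$clone_summary[rep$clone_summary$clone_id == "cl2", ]
  expect_equal(s2$via, "vector_end_proxy")
  expect_true(s2$anchored)
  expect_equal(rep$contig_map$clone_id[rep$contig_map$contig_id == "ctg2"], "cl2")
  expect_equal(nrow(rep$conflicts), 0)
})

test_that("pool contigs pair to the dominant singleton assembly", {
  lens <- c(pc1 = 10000, pc2 = 8000, pc3 = 5000)
  singleton_of <- c(sA1 = "A", sA2 = "A", sB1 = "B")
  hits <- rbind(
    # pc1: 99 % of its length on assembly A
    mk_hit("pc1", "sA1", 0, 9900, 5000),
    # pc2: split 60/40 between A and B by summed score
    mk_hit("pc2", "sA2", 0, 6000, 600),
    mk_hit("pc2", "sB1", 0, 4000, 400)
  )
  hits$query_end[1] <- 9900
  hits$query_end[2] <- 6000
  hits$query_end[3] <- 4000
  res <- pair_pool_to_singletons(hits, lens, singleton_of)
  expect_equal(res$paired_assembly[res$pool_contig == "pc1"], "A")
  expect_equal(res$status[res$pool_contig == "pc1"], "paired")
  r2 <- res[res$pool_contig == "pc2", ]
  expect_equal(r2$paired_assembly, "A")
  expect_equal(r2$status, "shared")
  # brute-force summed-score check
  expect_equal(r2$summed_bit_score, 600)
  expect_equal(res$status[res$pool_contig == "pc3"], "unpaired")
})
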