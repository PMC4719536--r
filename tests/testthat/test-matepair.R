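mk_mapped <- function(s1, e1, st1, s2, e2, st2, contig = "ctg",
                      id = 100, aligned = 150, read_len = 150, hits = 1) {
  data.frame(pair_id = "p", contig1 = contig, start1 = s1, end1 = e1,
             strand1 = st1, identity1 = id, aligned1 = aligned,
             read_len1 = read_len, hit_count1 = hits,
             contig2 = contig, start2 = s2, end2 = e2, strand2 = st2,
             identity2 = id, aligned2 = aligned, read_len2 = read_len,
             hit_count2 = hits, stringsAsFactors = FALSE)
}

test_that("orientation classes follow the leftmost/rightmost strand pattern", {
  rf <- classify_orientation(mk_mapped(1000, 1150, "-", 6850, 7000, "+"))
  expect_equal(rf$class, "RF")
  expect_equal(rf$insert_size, 6000L)
  fr <- classify_orientation(mk_mapped(1000, 1150, "+", 1250, 1400, "-"))
  expect_equal(fr$class, "FR")
  expect_equal(fr$insert_size, 400L)
  ff <- classify_orientation(mk_mapped(100, 250, "+", 900, 1050, "+"))
  expect_equal(ff$class, "FF_RR")
  rr <- classify_orientation(mk_mapped(900, 1050, "-", 100, 250, "-"))
  expect_equal(rr$class, "FF_RR")
  # classification is positional: swapping mate labels changes nothing
  swapped <- classify_orientation(mk_mapped(6850, 7000, "+", 1000, 1150, "-"))
  expect_equal(swapped$class, "RF")
  expect_equal(swapped$insert_size, 6000L)
  bad <- mk_mapped(1, 151, "+", 300, 450, "-")
  bad$contig2 <- "other"
  expect_error(classify_orientation(bad), "same contig")
})

test_that("orientation calls recover simulator truth for all interior pairs", {
  cl <- simulate_clone("mpref", length = 30000, repeat_fraction = 0.3,
                       seed = 61)
  cfg <- sim_config(seed = 62, mp_orientation_mix = c(0.9, 0.05, 0.05))
  mp <- simulate_mate_pairs(cl$insert, 3000, cfg)
  calls <- classify_orientation(mp_to_mapped(mp, cfg$read_length))
  # diagonal confusion matrix
  expect_equal(calls$class, mp$truth_class)
  expect_equal(calls$insert_size, mp$insert_size)
  # class partition: each pair in exactly one class, percentages sum to 100
  summ <- orientation_summary(calls)
  expect_equal(sum(summ$n), nrow(mp))
  expect_equal(sum(summ$pct), 100)
})

test_that("validation-pair selection enforces unique full-identity long mappings", {
  ok <- mk_mapped(100, 250, "-", 5000, 5150, "+")
  expect_equal(nrow(select_validation_pairs(ok)), 1)
  worse <- ok; worse$identity2 <- 99.9
  expect_equal(nrow(select_validation_pairs(worse)), 0)
  multi <- ok; multi$hit_count1 <- 2
  expect_equal(nrow(select_validation_pairs(multi)), 0)
  short <- ok; short$read_len1 <- 100  # strict: must exceed 100
  expect_equal(nrow(select_validation_pairs(short)), 0)
  cross <- ok; cross$contig2 <- "other"
  expect_equal(nrow(select_validation_pairs(cross)), 0)
})

test_that("orientation summary reports per-class percentages and medians", {
  calls <- data.frame(
    class = c(rep("RF", 990), rep("FR", 3), rep("FF_RR", 7)),
    insert_size = c(rep(6000L, 990), rep(400L, 3), rep(1000L, 7)),
    stringsAsFactors = FALSE
  )
  s <- orientation_summary(calls)
  expect_equal(s$pct[s$class == "RF"], 99.0)
  expect_equal(s$pct[s$class == "FR"], 0.3)
  expect_equal(s$pct[s$class == "FF_RR"], 0.7)

  allrf <- data.frame(class = rep("RF", 10),
                      insert_size = c(5999L, 6000L, 6001L, rep(6000L, 7)))
  s2 <- orientation_summary(allrf)
  expect_equal(s2$pct, c(100, 0, 0))
  expect_equal(s2$median_insert[1], 6000)
  expect_error(orientation_summary(allrf[0, ]), "no orientation calls")
})

test_that("shadow plus chimera fraction stays under the 3 % acceptance bound", {
  cl <- simulate_clone("mpref2", length = 30000, repeat_fraction = 0.2,
                       seed = 63)
  cfg <- sim_config(seed = 64, mp_orientation_mix = c(0.98, 0.01, 0.01))
  mp <- simulate_mate_pairs(cl$insert, 20000, cfg)
  summ <- orientation_summary(classify_orientation(mp_to_mapped(mp, 150)))
  expect_lt(sum(summ$pct[summ$class %in% c("FR", "FF_RR")]), 3)
})

test_that("scaffold-pair selection requires full-length perfect mappings in one pool", {
  ok <- mk_mapped(100, 250, "-", 5000, 5150, "+")
  expect_equal(nrow(select_scaffold_pairs(ok, 150)), 1)
  part <- ok; part$aligned1 <- 148
  expect_equal(nrow(select_scaffold_pairs(part, 150)), 0)
  # monotonicity: relaxing identity only grows the subset
  mixed <- rbind(ok, transform(ok, identity1 = 99.5))
  strict <- select_scaffold_pairs(mixed, 150)
  relaxed <- mixed[mixed$identity1 >= 99 & mixed$identity2 >= 99 &
                     mixed$aligned1 == 150 & mixed$aligned2 == 150, ]
  expect_true(all(strict$pair_id %in% relaxed$pair_id))
  # cross-pool pairs rejected
  cross <- ok; cross$contig2 <- "ctgB"
  pools <- c(ctg = "pool1", ctgB = "pool2")
  expect_equal(nrow(select_scaffold_pairs(cross, 150, pools)), 0)
  pools2 <- c(ctg = "pool1", ctgB = "pool1")
  expect_equal(nrow(select_scaffold_pairs(cross, 150, pools2)), 1)
})

test_that("SSPACE tab output uses 1-based inclusive coordinates deterministically", {
  links <- data.frame(pair_id = "p1", contig_a = "c1", start_a = 0L,
                      end_a = 150L, strand_a = "+", contig_b = "c2",
                      start_b = 300L, end_b = 450L, strand_b = "-",
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tab")
  write_sspace_tab(links, f)
  expect_equal(readLines(f), "c1\t1\t150\tc2\t301\t450")
  # empty links -> empty file
  write_sspace_tab(links[0, ], f)
  expect_equal(length(readLines(f)), 0)
  # determinism
  many <- links[rep(1, 5), ]
  many$start_a <- c(40L, 10L, 30L, 0L, 20L)
  f2 <- withr::local_tempfile(fileext = ".tab")
  write_sspace_tab(many, f)
  write_sspace_tab(many[sample(5), ], f2)
  expect_identical(readLines(f), readLines(f2))
  expect_error(write_sspace_tab(links, f, contig_lengths = c(c1 = 1000)),
               "unknown contig")
})

test_that("link bundling applies the K threshold and estimates gaps", {
  lens <- c(c1 = 20000, c2 = 20000, c3 = 20000)
  mk_link <- function(n, ca, cb) {
    data.frame(pair_id = sprintf("%s%s%02d", ca, cb, seq_len(n)),
               contig_a = ca, start_a = 19000L, end_a = 19150L,
               strand_a = "-", contig_b = cb, start_b = 5000L,
               end_b = 5150L, strand_b = "+", stringsAsFactors = FALSE)
  }
  links <- rbind(mk_link(12, "c1", "c2"), mk_link(9, "c1", "c3"))
  b <- bundle_links(links, lens, min_links = 10)
  expect_equal(nrow(b), 1)
  expect_equal(b$contig_a, "c1")
  expect_equal(b$contig_b, "c2")
  expect_equal(b$n_links, 12)
})

test_that("gap estimate recovers a constructed 500 bp gap within 200 bp", {
  cl <- simulate_clone("gapref", length = 40000, repeat_fraction = 0,
                       repeat_unit_length = 500, seed = 71)
  # a tight insert distribution: the estimator assumes the configured
  # insert mean matches the spanning pairs' mean, which wide libraries
  # violate through length-biased sampling of gap-spanning pairs
  cfg <- sim_config(seed = 72, mp_orientation_mix = c(1, 0, 0),
                    mp_insert_min = 6000, mp_insert_max = 7000)
  mp <- simulate_mate_pairs(cl$insert, 3000, cfg)
  links <- split_reference_links(mp, break_at = 20000, gap = 500,
                                 ref_length = 40000)
  lens <- c(c1 = 20000, c2 = 40000 - 20000 - 500)
  b <- bundle_links(links, lens, min_links = 10,
                    insert_range = c(cfg$mp_insert_min, cfg$mp_insert_max))
  inter <- b[b$contig_a != b$contig_b, ]
  expect_equal(nrow(inter), 1)
  expect_gt(inter$n_links, 50)
  expect_lt(abs(inter$gap_estimate - 500), 200)
})
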