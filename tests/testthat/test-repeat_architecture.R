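test_that("inverted-pair filtering is inclusive, idempotent and monotone", {
  pairs <- data.frame(seq_id = "chrX",
                      left_start = c(0, 100, 200), left_end = c(50, 150, 250),
                      right_start = c(500, 600, 700),
                      right_end = c(550, 650, 750),
                      percent_identity = c(94.9, 95.0, 99.0))
  kept <- filter_inverted_pairs(pairs)
  expect_equal(kept$percent_identity, c(95.0, 99.0))
  expect_equal(attr(kept, "rejected"), 1L)
  expect_equal(filter_inverted_pairs(kept)$percent_identity,
               kept$percent_identity)
  sizes <- vapply(c(90, 95, 99, 99.5), function(mi)
    nrow(filter_inverted_pairs(pairs, mi)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  ## simulated identities straddling the threshold
  sim_pairs <- data.frame(seq_id = "c", left_start = 0, left_end = 10,
                          right_start = 20, right_end = 30,
                          percent_identity = c(90, 95, 99))
  expect_equal(filter_inverted_pairs(sim_pairs)$percent_identity, c(95, 99))
})

test_that("inverted coverage counts arm unions once", {
  pairs <- data.frame(seq_id = "chrX", left_start = 0, left_end = 100,
                      right_start = 900, right_end = 1000,
                      percent_identity = 99)
  cov <- inverted_coverage(pairs, list(seq_id = "chrX", start = 0,
                                       end = 1000))
  expect_equal(cov$arm_fraction, 0.2)
  expect_equal(cov$span_fraction, 1.0)
  ## nested/overlapping arms: union equals the mask oracle
  p2 <- data.frame(seq_id = "chrX",
                   left_start = c(0, 50), left_end = c(100, 120),
                   right_start = c(800, 840), right_end = c(900, 950),
                   percent_identity = 99)
  cov2 <- inverted_coverage(p2, list(seq_id = "chrX", start = 0, end = 1000))
  arms <- genomic_interval("chrX", c(0, 50, 800, 840), c(100, 120, 900, 950))
  expect_equal(cov2$covered_bp, mask_union_length(arms))
  empty <- inverted_coverage(p2[0, ], list(seq_id = "chrX", start = 0,
                                           end = 1000))
  expect_equal(empty$arm_fraction, 0)
})

test_that("simulated neocentromere pairs are recovered through the IRF dialect", {
  ts <- tiny_sim()
  truth <- ts$sim$truth$inverted_pairs
  f <- withr::local_tempfile()
  writeLines(c("@chrX",
               sprintf("%d %d %d %d %.2f", truth$left_start + 1,
                       truth$left_end, truth$right_start + 1,
                       truth$right_end, truth$percent_identity)), f)
  pairs <- read_annotations(f, "irf_ngs")
  expect_equal(pairs$left_start, truth$left_start)
  expect_equal(pairs$right_end, truth$right_end)
  kept <- filter_inverted_pairs(pairs, 95)
  expect_equal(nrow(kept), nrow(truth))
  neo <- ts$sim$truth$centromeres
  neo <- neo[neo$seq_id == "chrX", ]
  cov <- inverted_coverage(kept, list(seq_id = "chrX", start = neo$start,
                                      end = neo$end))
  expected_arm_bp <- sum(truth$left_end - truth$left_start +
                           truth$right_end - truth$right_start)
  expect_equal(cov$covered_bp, expected_arm_bp)
})

test_that("nesting requires both arms covered by the largest arm's hits", {
  pairs <- data.frame(seq_id = "chrX",
                      left_start = c(0, 2000, 3000),
                      left_end = c(1000, 2100, 3100),
                      right_start = c(8000, 2500, 9000),
                      right_end = c(9000, 2600, 9100),
                      percent_identity = 99)
  ## hits cover pair 2 fully; pair 3 only on one arm
  hits <- data.frame(seq_id = "chrX", start = c(1900, 2450, 2950),
                     end = c(2200, 2700, 3050))
  out <- classify_nesting(pairs, hits)
  expect_equal(attr(out, "largest"), 1L)
  expect_identical(out$nested, c(FALSE, TRUE, FALSE))
  ## planted nesting: 3 of 10 smaller pairs covered
  withr::with_seed(83, {
    p <- data.frame(seq_id = "c",
                    left_start = seq(0, 9000, by = 1000),
                    right_start = seq(20000, 29000, by = 1000))
    p$left_end <- p$left_start + 200
    p$right_end <- p$right_start + 200
    p$percent_identity <- 99
    p$left_end[1] <- p$left_start[1] + 5000  # pair 1 is the largest
    nested_idx <- c(3L, 5L, 8L)
    h <- do.call(rbind, lapply(nested_idx, function(i) {
      data.frame(seq_id = "c",
                 start = c(p$left_start[i], p$right_start[i]),
                 end = c(p$left_end[i], p$right_end[i]))
    }))
    out2 <- classify_nesting(p, h)
    expect_identical(which(out2$nested), nested_idx)
  })
})

test_that("tandem unit coverage reproduces the centromere arithmetic", {
  region <- list(seq_id = "chrX", start = 38000000, end = 50000000)
  ## nine disjoint 318 kb copies in the 12 Mb centromere
  starts <- 38000000 + (0:8) * 400000
  hits9 <- data.frame(query_id = "XCTR3", seq_id = "chrX", start = starts,
                      end = starts + 318000, strand = "+",
                      percent_identity = 99, evalue = 0,
                      query_coverage = 1)
  s9 <- tandem_unit_stats(hits9, region, unit_name = "XCTR3",
                          unit_length = 318000)
  expect_equal(s9$copy_count, 9L)
  expect_equal(s9$coverage_fraction, 9 * 318000 / 12e6)
  expect_equal(round(s9$coverage_percent), 24)
  ## 111 x 2898 bp plus 106 x 6558 bp
  st1 <- 38000000 + (0:110) * 20000
  st2 <- 41000000 + (0:105) * 20000
  hits_sm <- rbind(
    data.frame(query_id = "XCTR1", seq_id = "chrX", start = st1,
               end = st1 + 2898, strand = "+", percent_identity = 95,
               evalue = 0, query_coverage = 1),
    data.frame(query_id = "XCTR2", seq_id = "chrX", start = st2,
               end = st2 + 6558, strand = "+", percent_identity = 95,
               evalue = 0, query_coverage = 1))
  s_sm <- tandem_unit_stats(hits_sm, region, unit_name = "XCTR1+2")
  expect_equal(s_sm$copy_count, 217L)
  expect_equal(s_sm$coverage_percent, 8.5)
  ## identity/coverage thresholds drop copies
  weak <- hits9; weak$percent_identity <- 80
  expect_equal(tandem_unit_stats(weak, region)$copy_count, 0L)
  ## overlapping hits: covered bp equals the mask oracle
  ov <- data.frame(query_id = "u", seq_id = "c",
                   start = c(0, 500, 900), end = c(1000, 1500, 2000),
                   strand = "+", percent_identity = 99, evalue = 0,
                   query_coverage = 1)
  s_ov <- tandem_unit_stats(ov, list(seq_id = "c", start = 0, end = 5000))
  expect_equal(s_ov$covered_bp,
               mask_union_length(genomic_interval("c", c(0, 500, 900),
                                                  c(1000, 1500, 2000))))
})

test_that("rDNA unit detection enforces order, thresholds and orientation", {
  t1 <- synthetic_rdna_truth(1)
  hits <- rdna_hits_from_truth(list(subunits = t1$subunits))
  units <- detect_rdna_units(hits)
  expect_equal(nrow(units), 1)
  expect_identical(units$orientation, "+")
  ## wrong order: 5.8S -> 18S -> 28S
  bad <- hits
  bad$query_id <- c("5.8S", "18S", "28S")
  expect_equal(nrow(detect_rdna_units(bad)), 0)
  ## identity below threshold on one subunit breaks the unit
  weak <- hits; weak$percent_identity[1] <- 80
  expect_equal(nrow(detect_rdna_units(weak)), 0)
  ## minus-strand unit: 28S -> 5.8S -> 18S in coordinate order
  rev_hits <- hits
  rev_hits$query_id <- c("28S", "5.8S", "18S")
  rev_hits$strand <- "-"
  units_m <- detect_rdna_units(rev_hits)
  expect_equal(nrow(units_m), 1)
  expect_identical(units_m$orientation, "-")
  ## an excessive intra-unit gap breaks chaining
  far <- hits
  far$start[3] <- far$start[3] + 1e5
  far$end[3] <- far$end[3] + 1e5
  expect_equal(nrow(detect_rdna_units(far)), 0)
})

test_that("planted rDNA arrays are recovered for k in {0, 1, 5, 20}", {
  for (k in c(0, 1, 5, 20)) {
    tr <- synthetic_rdna_truth(k)
    hits <- rdna_hits_from_truth(list(subunits = tr$subunits))
    expect_equal(nrow(detect_rdna_units(hits)), k)
  }
  ## degraded units below threshold are dropped
  tr <- synthetic_rdna_truth(5)
  hits <- rdna_hits_from_truth(list(subunits = tr$subunits))
  degrade <- hits$query_id == "5.8S" &
    hits$start %in% tr$subunits$start[tr$subunits$unit %in% c(2, 4)]
  hits$percent_identity[degrade] <- 70
  expect_equal(nrow(detect_rdna_units(hits)), 3)
  ## end-to-end on the simulated genome's planted array
  ts <- tiny_sim()
  sim_hits <- rdna_hits_from_truth(ts$sim$truth$rdna)
  expect_equal(nrow(detect_rdna_units(sim_hits)),
               nrow(ts$sim$truth$rdna$units))
})
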