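test_that("window medians match a brute-force recomputation", {
  withr::with_seed(61, {
    recs <- data.frame(seq_id = "chr1",
                       start = sort(sample(0:99998, 10000)),
                       coverage = 30, platform = "ONT",
                       meth_fraction = stats::runif(10000))
    recs$end <- recs$start + 2
  })
  wm <- window_methylation(recs, window = 10000, step = 5000, min_cpgs = 10,
                           chrom_lengths = c(chr1 = 100000))
  brute <- vapply(seq_len(nrow(wm)), function(i) {
    sel <- recs$start >= wm$window_start[i] & recs$start < wm$window_end[i]
    stats::median(recs$meth_fraction[sel])
  }, numeric(1))
  expect_equal(wm$median_meth, brute)
  ## single-window degenerate cases
  one <- data.frame(seq_id = "c", start = 1:100, end = 3:102, coverage = 1,
                    meth_fraction = 0.8, platform = "ONT")
  w1 <- window_methylation(one, window = 1000, step = 1000,
                           chrom_lengths = c(c = 1000))
  expect_equal(w1$median_meth, 0.8)
  few <- one[1:3, ]
  w0 <- window_methylation(few, window = 1000, step = 1000, min_cpgs = 10,
                           chrom_lengths = c(c = 1000))
  expect_equal(nrow(w0), 0)
  expect_equal(attr(w0, "dropped"), 1L)
})

test_that("compartment comparison direction, ties and input order", {
  withr::with_seed(67, {
    recs <- planted_methylation(1e6, 4e5, 5e5, mean_arm = 0.8, delta = -0.1)
  })
  wm <- window_methylation(recs, window = 1e4, step = 5e3)
  cc <- compare_compartments(wm, list(start = 4e5, end = 5e5))
  expect_true(cc$testable)
  expect_lt(cc$p_two_sided, 0.05)
  expect_identical(cc$direction, "cen_lower")
  expect_lt(cc$median_cen, cc$median_noncen)
  ## record order must not matter
  withr::with_seed(68, wm2 <- wm[sample(nrow(wm)), ])
  cc2 <- compare_compartments(wm2, list(start = 4e5, end = 5e5))
  expect_equal(cc$p_two_sided, cc2$p_two_sided)
  ## all-identical window values: p = 1 through the tie path
  tied <- wm; tied$median_meth <- 0.5
  cct <- compare_compartments(tied, list(start = 4e5, end = 5e5))
  expect_equal(cct$p_two_sided, 1)
  expect_identical(cct$direction, "none")
  ## an empty compartment is flagged untestable
  cce <- compare_compartments(wm, list(start = 2e6, end = 3e6))
  expect_false(cce$testable)
  expect_true(is.na(cce$p_two_sided))
})

test_that("Mann-Whitney path agrees with exact rank enumeration for small groups", {
  ## enumeration oracle: exact two-sided p over all assignments
  exact_mw <- function(x, y) {
    all_v <- c(x, y); n <- length(x)
    combos <- utils::combn(length(all_v), n)
    r_obs <- sum(rank(all_v)[seq_len(n)])
    rs <- apply(combos, 2, function(idx) sum(rank(all_v)[idx]))
    mu <- n * (length(all_v) + 1) / 2
    mean(abs(rs - mu) >= abs(r_obs - mu) - 1e-9)
  }
  withr::with_seed(71, {
    for (rep in 1:10) {
      x <- stats::runif(sample(4:8, 1))
      y <- stats::runif(sample(4:8, 1))
      wm <- data.frame(
        seq_id = "c", platform = "ONT",
        window_start = seq(0, length.out = length(x) + length(y), by = 100),
        window_end = seq(100, length.out = length(x) + length(y), by = 100),
        n_cpgs = 50, median_meth = c(x, y))
      cc <- compare_compartments(wm, list(start = 0,
                                          end = 100 * length(x)))
      expect_equal(cc$p_two_sided, exact_mw(x, y), tolerance = 1e-9)
    }
  })
})

test_that("planted methylation shift is detected and the null is calibrated", {
  ## power: delta = -0.10 found in almost every seed
  hits <- vapply(1:100, function(sd) {
    withr::with_seed(1000 + sd, {
      recs <- planted_methylation(5e5, 2e5, 3e5, mean_arm = 0.8,
                                  delta = -0.1)
    })
    wm <- window_methylation(recs, window = 1e4, step = 5e3)
    cc <- compare_compartments(wm, list(start = 2e5, end = 3e5))
    cc$testable && !is.na(cc$p_two_sided) && cc$p_two_sided < 0.05 &&
      cc$direction == "cen_lower"
  }, logical(1))
  expect_gte(sum(hits), 95)
  ## calibration: delta = 0 gives approximately uniform p. Non-overlapping
  ## windows keep the medians independent, and 100 windows per seed put the
  ## comparison on the near-continuous rank-sum path.
  ps <- vapply(1:1000, function(sd) {
    withr::with_seed(3000 + sd, {
      recs <- planted_methylation(1e6, 4e5, 6e5, mean_arm = 0.8,
                                  delta = 0, spacing = 200)
    })
    wm <- window_methylation(recs, window = 1e4, step = 1e4)
    compare_compartments(wm, list(start = 4e5, end = 6e5))$p_two_sided
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.1)
})

test_that("detection rate grows with centromere span", {
  rate_for_span <- function(span) {
    mean(vapply(1:20, function(sd) {
      withr::with_seed(5000 + sd, {
        recs <- planted_methylation(1e6, 5e5 - span / 2, 5e5 + span / 2,
                                    mean_arm = 0.8, delta = -0.1,
                                    spacing = 200, dispersion = 6)
      })
      wm <- window_methylation(recs, window = 2e4, step = 1e4, min_cpgs = 5)
      cc <- compare_compartments(wm, list(start = 5e5 - span / 2,
                                          end = 5e5 + span / 2))
      cc$testable && !is.na(cc$p_two_sided) && cc$p_two_sided < 0.05
    }, logical(1)))
  }
  rates <- vapply(c(1e4, 5e4, 1e5), rate_for_span, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("window-size scan reports per-size significant counts", {
  withr::with_seed(73, {
    recs <- planted_methylation(5e5, 2e5, 3e5, mean_arm = 0.8, delta = -0.1)
  })
  calls <- data.frame(seq_id = "chr1", start = 2e5, end = 3e5)
  tab <- scan_window_sizes(recs, calls, sizes = c(1e4, 5e4, 1e5),
                           chrom_lengths = c(chr1 = 5e5))
  expect_equal(nrow(tab), 3)
  expect_true(any(tab$n_significant > 0))
  empty <- scan_window_sizes(recs, calls[0, ], sizes = 1e4)
  expect_equal(nrow(empty), 0)
  expect_identical(unique(tab$platform), "ONT")
})

test_that("CENP-A per-family signal finds the planted enrichment", {
  ts <- tiny_sim()
  reps <- ts$sim$repeats[ts$sim$repeats$repeat_class == "satellite", ]
  peaks <- simulate_cenpa_peaks(reps, enrich_family = "SATVI",
                                peaks_per_kb = 0.3, enrich_factor = 8,
                                seed = 12)
  sig <- cenpa_satellite_signal(peaks, reps)
  expect_identical(sig$per_family$family[1], "SATVI")
  expect_false(is.null(sig$kruskal))
  expect_lt(sig$kruskal$p_value, 0.05)
  ## a peak with no repeat overlap is unassigned and excluded
  stray <- rbind(peaks, data.frame(seq_id = "chr1", start = 390000,
                                   end = 390200, score = 5))
  sig2 <- cenpa_satellite_signal(stray, reps)
  expect_equal(sig2$n_unassigned, 1L)
  expect_equal(sum(sig2$per_family$n_peaks), nrow(peaks))
})
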