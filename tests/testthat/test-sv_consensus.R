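mk_call <- function(seq_id, start, type, len, caller, sample,
                    genotype = "0/1") {
  data.frame(seq_id = seq_id, start = start,
             end = if (type == "INS") start + 1 else start + len,
             sv_type = type, length = len, caller = caller, sample = sample,
             genotype = genotype, stringsAsFactors = FALSE)
}

test_that("calls merge within tolerance and split across types", {
  calls <- rbind(mk_call("chr1", 1000, "DEL", 1000, "Sniffles2", "S1"),
                 mk_call("chr1", 1500, "DEL", 950, "cuteSV", "S1"),
                 mk_call("chr1", 1200, "INS", 980, "SVIM", "S1"))
  cons <- merge_calls(calls)
  expect_equal(nrow(cons$records), 2)
  del <- cons$records[cons$records$sv_type == "DEL", ]
  expect_equal(del$n_callers, 2)
  expect_equal(del$start, 1250)
  expect_equal(del$length, 975)
  ## size ratio splits very different lengths
  calls2 <- rbind(mk_call("chr1", 1000, "DEL", 1000, "Sniffles2", "S1"),
                  mk_call("chr1", 1100, "DEL", 100, "cuteSV", "S1"))
  expect_equal(nrow(merge_calls(calls2)$records), 2)
  ## Y-chromosome calls are dropped
  callsY <- rbind(mk_call("chrY", 500, "DEL", 100, "SVIM", "S1"),
                  mk_call("chr1", 500, "DEL", 100, "SVIM", "S1"))
  expect_equal(merge_calls(callsY)$records$seq_id, "chr1")
})

test_that("merging is idempotent on its own representatives", {
  withr::with_seed(103, {
    calls <- do.call(rbind, lapply(1:50, function(i) {
      base <- i * 5000
      do.call(rbind, lapply(1:3, function(j)
        mk_call("chr1", base + sample(-300:300, 1), "DEL",
                1000 + sample(-50:50, 1), c("Sniffles2", "cuteSV", "SVIM")[j],
                sprintf("S%d", j))))
    }))
  })
  cons <- merge_calls(calls)
  again <- merge_calls(cons$records)
  expect_equal(nrow(again$records), nrow(cons$records))
  expect_equal(again$records$start, cons$records$start)
})

test_that("high-confidence filter enforces per-sample caller support", {
  calls <- rbind(
    ## record A: 3 callers, 1 sample -> dropped
    mk_call("chr1", 1000, "DEL", 500, "Sniffles2", "S1"),
    mk_call("chr1", 1010, "DEL", 500, "cuteSV", "S1"),
    mk_call("chr1", 1020, "DEL", 500, "SVIM", "S1"),
    ## record B: 2 callers in each of 2 samples -> kept
    mk_call("chr1", 50000, "INS", 300, "Sniffles2", "S1"),
    mk_call("chr1", 50010, "INS", 300, "cuteSV", "S1"),
    mk_call("chr1", 50005, "INS", 300, "Sniffles2", "S2"),
    mk_call("chr1", 50015, "INS", 300, "SVIM", "S2"),
    ## record C: 1 caller in each of 2 samples -> dropped per-sample,
    ## kept under the relaxed reading
    mk_call("chr1", 90000, "DUP", 700, "Sniffles2", "S1"),
    mk_call("chr1", 90010, "DUP", 700, "cuteSV", "S2"))
  cons <- merge_calls(calls)
  hc <- high_confidence_filter(cons)
  expect_equal(nrow(hc$records), 1)
  expect_equal(hc$records$sv_type, "INS")
  relaxed <- high_confidence_filter(cons, per_sample = FALSE)
  expect_setequal(relaxed$records$sv_type, c("INS", "DUP"))
  ## monotonicity: stricter thresholds keep a subset
  withr::with_seed(107, {
    many <- do.call(rbind, lapply(1:100, function(i) {
      n <- sample(1:4, 1)
      do.call(rbind, lapply(1:n, function(j)
        mk_call("chr1", i * 4000, "DEL", 400,
                sample(c("Sniffles2", "cuteSV", "SVIM", "DYSGU"), 1),
                sprintf("S%d", sample(1:4, 1)))))
    }))
  })
  consm <- merge_calls(many)
  k2 <- high_confidence_filter(consm, min_callers = 2)$records$record_id
  k3 <- high_confidence_filter(consm, min_callers = 3)$records$record_id
  expect_true(all(k3 %in% k2))
})

test_that("genotypes resolve by caller priority with DYSGU fallback", {
  expect_equal(resolve_genotype(c(Sniffles2 = "0/1", cuteSV = "1/1"))$genotype,
               "0/1")
  expect_equal(resolve_genotype(c(cuteSV = "1/1", Sniffles2 = "0/1"))$genotype,
               "0/1")
  one <- resolve_genotype(c(SVIM = "1/1"))
  expect_equal(one$genotype, "1/1")
  expect_false(one$fallback)
  fb <- resolve_genotype(c(DYSGU = "0/1"))
  expect_equal(fb$genotype, "0/1")
  expect_true(fb$fallback)
  expect_equal(resolve_genotype(character(0))$genotype, "./.")
})

test_that("region classification follows the precedence ladder", {
  ann <- data.frame(
    seq_id = "chr1",
    start = c(10000, 10000, 12500, 10000, 14800),
    end = c(15000, 11000, 13000, 10200, 15000),
    type = c("gene", "exon", "exon", "five_prime_UTR", "three_prime_UTR"),
    strand = "+")
  cls <- function(s, e) classify_region(list(seq_id = "chr1", start = s,
                                             end = e), ann)
  expect_equal(cls(10500, 10600), "exonic")
  ## within 1 kb of the TSS but also exonic -> exonic wins
  expect_equal(cls(9900, 10100), "exonic")
  expect_equal(cls(11001, 11002), "splicing")
  expect_equal(cls(11500, 11600), "intronic")
  expect_equal(cls(9500, 9600), "upstream_1kb")
  expect_equal(cls(15100, 15200), "downstream_1kb")
  expect_equal(cls(50000, 50100), "intergenic")
  ## minus-strand gene flips the flanks
  ann_m <- data.frame(seq_id = "chr1", start = 30000, end = 35000,
                      type = "gene", strand = "-")
  expect_equal(classify_region(list(seq_id = "chr1", start = 35100,
                                    end = 35200), ann_m), "upstream_1kb")
  expect_equal(classify_region(list(seq_id = "chr1", start = 29500,
                                    end = 29600), ann_m), "downstream_1kb")
})

test_that("length distribution modes recover planted mixture centers", {
  withr::with_seed(109, {
    lens <- c(round(stats::rlnorm(600, log(145), 0.12)),
              round(stats::rlnorm(400, log(1300), 0.15)))
    recs <- data.frame(sv_type = "INS", length = lens)
  })
  ld <- length_distribution(recs, types = "INS")
  modes <- ld$INS$modes_bp
  expect_equal(length(modes), 2)
  expect_lt(abs(modes[1] - 145) / 145, 0.15)
  expect_lt(abs(modes[2] - 1300) / 1300, 0.15)
  ## single repeated value degenerates to one mode
  single <- data.frame(sv_type = "DEL", length = rep(300, 20))
  expect_equal(length_distribution(single, types = "DEL")$DEL$modes_bp, 300)
  ## record order invariance
  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  expect_equal(length_distribution(shuffled, types = "INS")$INS$modes_bp,
               modes)
  expect_warning(length_distribution(data.frame(sv_type = "DEL",
                                                length = c(60, 70)),
                                     types = "DEL"), "skipped")
})

test_that("end-to-end consensus recovers simulated truth with low FDR", {
  recalls <- numeric(0); fdrs <- numeric(0)
  for (sd in 1:10) {
    cfg <- sim_config(seed = sd, n_chromosomes = 2L, chrom_length = 5e5,
                      centromere_span = 5e4, x_chromosome = FALSE,
                      rdna_spec = list(n_units = 0),
                      sv_spec = list(n_sv = c(INS = 60, DEL = 60, INV = 15,
                                              DUP = 15),
                                     sensitivity = 0.95, false_rate = 0.05,
                                     n_samples = 20, allele_freq = 0.3,
                                     pos_jitter = 200))
    sim <- simulate_genome(cfg)
    truth <- sim$truth$svs
    calls <- simulate_sv_callsets(truth, cfg$sv_spec, seed = sd * 13)
    cons <- merge_calls(calls, drop_chroms = character(0))
    hc <- high_confidence_filter(cons)
    matched <- vapply(seq_len(nrow(truth$table)), function(i) {
      any(hc$records$seq_id == truth$table$seq_id[i] &
            hc$records$sv_type == truth$table$sv_type[i] &
            abs(hc$records$start - truth$table$start[i]) <= 1000)
    }, logical(1))
    rec_matched <- vapply(seq_len(nrow(hc$records)), function(i) {
      any(truth$table$seq_id == hc$records$seq_id[i] &
            truth$table$sv_type == hc$records$sv_type[i] &
            abs(truth$table$start - hc$records$start[i]) <= 1000)
    }, logical(1))
    recalls <- c(recalls, mean(matched))
    fdrs <- c(fdrs, 1 - mean(rec_matched))
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(mean(fdrs), 0.05)
})

test_that("SV tables round-trip through the TSV reader", {
  calls <- rbind(mk_call("chr1", 100, "DEL", 60, "Sniffles2", "S1"),
                 mk_call("chr2", 900, "INS", 200, "cuteSV", "S2", "1/1"))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(calls, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_sv_table(f)
  expect_equal(back, calls)
  ## headerless variant
  utils::write.table(calls, f, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  back2 <- read_sv_table(f)
  expect_equal(back2$start, calls$start)
})
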