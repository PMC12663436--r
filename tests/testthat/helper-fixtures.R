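## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, fn(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## small full simulation: 2 acrocentric chromosomes + X-like neocentromere
tiny_sim <- function() {
  cached("tiny_sim", function() {
    cfg <- sim_config(seed = 11L, n_chromosomes = 3L, chrom_length = 4e5,
                      centromere_span = 1e5, telomere_tract_len = 2000,
                      neocentromere_spec = list(span = 1.2e5, n_pairs = 4,
                                                arm_len = 3000,
                                                target_identity = 99,
                                                deamination_rate = 0.8),
                      rdna_spec = list(n_units = 2),
                      sv_spec = list(n_sv = c(INS = 20, DEL = 20, INV = 5,
                                              DUP = 5), n_samples = 6))
    list(config = cfg, sim = simulate_genome(cfg))
  })
}

## acrocentric-only multi-chromosome simulation for boundary recovery
acro_sim <- function(seed) {
  cfg <- sim_config(seed = seed, n_chromosomes = 5L, chrom_length = 2e5,
                    centromere_span = 6e4, telomere_tract_len = 2000,
                    x_chromosome = FALSE,
                    rdna_spec = list(n_units = 0),
                    sv_spec = list(n_sv = c(INS = 0)), n_genes = 0L)
  simulate_genome(cfg)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## brute-force position-mask union length oracle
mask_union_length <- function(intervals) {
  if (nrow(intervals) == 0) return(0L)
  span <- max(intervals$end)
  mask <- logical(span)
  for (i in seq_len(nrow(intervals)))
    mask[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  sum(mask)
}

## direct per-sample methylation record generator for planted-shift tests
## (window medians are what the comparison consumes; no genome is needed)
planted_methylation <- function(chrom_len, cen_start, cen_end, mean_arm,
                                delta, spacing = 50, dispersion = 30,
                                platform = "ONT") {
  pos <- seq(0, chrom_len - 2, by = spacing)
  mu <- ifelse(pos >= cen_start & pos < cen_end, mean_arm + delta, mean_arm)
  data.frame(seq_id = "chr1", start = pos, end = pos + 2,
             coverage = 30,
             meth_fraction = stats::rbeta(length(pos), mu * dispersion,
                                          (1 - mu) * dispersion),
             platform = platform, stringsAsFactors = FALSE)
}

## arithmetic rDNA truth: k units of ordered 18S/5.8S/28S blocks
synthetic_rdna_truth <- function(k, seq_id = "chr1", unit_gap = 20000) {
  if (k == 0)
    return(list(subunits = data.frame(seq_id = character(), unit = integer(),
                                      subunit = character(),
                                      start = numeric(), end = numeric())))
  lens <- c(`18S` = 1800, `5.8S` = 160, `28S` = 4700)
  rows <- list()
  offset <- 0
  for (u in seq_len(k)) {
    for (nm in names(lens)) {
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = seq_id, unit = u, subunit = nm, start = offset,
        end = offset + lens[[nm]], stringsAsFactors = FALSE)
      offset <- offset + lens[[nm]] + 2000
    }
    offset <- offset + unit_gap
  }
  list(subunits = do.call(rbind, rows))
}
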