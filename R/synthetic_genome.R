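## Synthetic genomes with planted centromeres, telomeres, inverted repeats,
## rDNA arrays, methylation and SV callsets. Every stochastic draw is fixed by
## the config seed; identical configs give byte-identical output.

.BASES <- c("A", "C", "G", "T")

.rand_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## substitute bases at iid rate; substitutions always change the base
.mutate <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, NULL)[[1]]
  hit <- which(stats::runif(length(ch)) < rate & ch %in% .BASES)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(.BASES, b), 1), "",
                      USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

## tandem monomer copies truncated to an exact target length
.tandem <- function(monomer, len) {
  n <- ceiling(len / nchar(monomer))
  substr(strrep(monomer, n), 1, len)
}

#' Default bovine-style satellite monomer library
#'
#' Seven satellite families with monomer lengths typical of the bovine
#' centromeric satellites (SATIII/SATV are short 23 bp monomers; SATVII is the
#' short 93 bp family found proximal to the telomere). Monomer sequences are
#' arbitrary but fixed: the same library is returned on every call.
#'
#' @return named list of monomer strings (names SATI..SATVII).
#' @export
default_satellite_library <- function() {
  lens <- c(SATI = 1400L, SATII = 700L, SATIII = 23L, SATIV = 680L,
            SATV = 23L, SATVI = 680L, SATVII = 93L)
  withr::with_seed(987654L, {
    lapply(lens, .rand_dna)
  })
}

#' Build a simulation configuration
#'
#' Defaults describe the scaled-down study system the package's tests use:
#' three ~1 Mb chromosomes, two acrocentric autosome-like chromosomes with
#' satellite centromeres (one in each structural grammar) and one
#' submetacentric X-like chromosome carrying a satellite-free neocentromere of
#' high-identity inverted repeats with CpG deamination, a lowered centromeric
#' methylation mean, and multi-caller / multi-sample SV callsets.
#'
#' @param seed integer; fixes every downstream draw.
#' @param n_chromosomes number of chromosomes (the last is the X-like
#'   neocentromere chromosome when `x_chromosome` is TRUE).
#' @param chrom_length chromosome length in bp.
#' @param telomere_unit telomeric repeat unit.
#' @param telomere_tract_len telomere tract length in bp (0 disables an end;
#'   may be a vector recycled over chromosomes, or a list of c(p, q) pairs).
#' @param gap_spec list of `list(chrom=, position=, length=)` N-gap insertions.
#' @param satellite_library named list family -> monomer string.
#' @param centromere_grammar character vector recycled over acrocentric
#'   chromosomes; values `"structure1"` (interspersed SATI/SATVI core) or
#'   `"structure2"` (single SATI->SATVI transition).
#' @param centromere_span satellite centromere span in bp.
#' @param x_chromosome logical; plant a neocentromere chromosome.
#' @param neocentromere_spec list: `span`, `n_pairs`, `arm_len`,
#'   `target_identity` (percent), `te_fraction`, `deamination_rate`.
#' @param rdna_spec list: `n_units`, `len_18s`, `len_5p8s`, `len_28s`,
#'   `spacer_min`, `spacer_max` (intra-unit spacers drawn uniformly).
#' @param methylation_spec list: `mean_arm`, `mean_centromere`, `dispersion`
#'   (Beta precision; larger = tighter), `mean_coverage`.
#' @param sv_spec list: `n_sv` (named by type), `callers`, `sensitivity`,
#'   `false_rate`, `n_samples`, `allele_freq`, `pos_jitter`,
#'   `genotype_error`, `min_len`, `max_len`.
#' @param n_genes genes planted per chromosome.
#' @return A validated config list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_length = 1e6,
                       telomere_unit = "TTAGGG",
                       telomere_tract_len = 3000,
                       gap_spec = list(),
                       satellite_library = default_satellite_library(),
                       centromere_grammar = c("structure1", "structure2"),
                       centromere_span = 2e5,
                       x_chromosome = TRUE,
                       neocentromere_spec = list(),
                       rdna_spec = list(),
                       methylation_spec = list(),
                       sv_spec = list(),
                       n_genes = 8L) {
  neo <- utils::modifyList(list(span = 2e5, n_pairs = 5, arm_len = 5000,
                                target_identity = 99, te_fraction = 0.5,
                                deamination_rate = 0.8), neocentromere_spec)
  rdna <- utils::modifyList(list(n_units = 3, len_18s = 1800, len_5p8s = 160,
                                 len_28s = 4700, spacer_min = 1000,
                                 spacer_max = 3000), rdna_spec)
  meth <- utils::modifyList(list(mean_arm = 0.8, mean_centromere = 0.7,
                                 dispersion = 100, mean_coverage = 30),
                            methylation_spec)
  sv <- utils::modifyList(list(n_sv = c(INS = 50, DEL = 50, INV = 10, DUP = 10),
                               callers = c("Sniffles2", "cuteSV", "SVIM", "DYSGU"),
                               sensitivity = 0.9, false_rate = 0.05,
                               n_samples = 10, allele_freq = 0.3,
                               pos_jitter = 100, genotype_error = 0.05,
                               min_len = 50, max_len = 10000), sv_spec)
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, telomere_unit = telomere_unit,
              telomere_tract_len = telomere_tract_len, gap_spec = gap_spec,
              satellite_library = satellite_library,
              centromere_grammar = centromere_grammar,
              centromere_span = centromere_span,
              x_chromosome = isTRUE(x_chromosome),
              neocentromere_spec = neo, rdna_spec = rdna,
              methylation_spec = meth, sv_spec = sv,
              n_genes = as.integer(n_genes))
  rates <- c(neo$deamination_rate, neo$te_fraction, sv$sensitivity,
             sv$false_rate, sv$allele_freq, sv$genotype_error,
             meth$mean_arm, meth$mean_centromere)
  if (any(rates < 0 | rates > 1)) stop("sim_config: all rates must be in [0,1]")
  if (chrom_length <= 0 || centromere_span <= 0 || neo$span <= 0)
    stop("sim_config: lengths must be positive")
  if (centromere_span + 2 * max(telomere_tract_len) + 2e4 > chrom_length)
    stop("sim_config: centromere span exceeds chromosome length")
  if (cfg$x_chromosome &&
      neo$span + 2 * max(telomere_tract_len) + 2e4 > chrom_length)
    stop("sim_config: neocentromere span exceeds chromosome length")
  structure(cfg, class = "sim_config")
}

#' Deaminate CpG sites in a sequence
#'
#' Each CpG dinucleotide is independently converted with probability `rate`:
#' to TpG (forward-strand C to T) with probability `rate/2` and to CpA
#' (reverse-strand deamination, G to A) with probability `rate/2`. In
#' single-strand mode every conversion is C to T (TpG product only).
#' Non-CpG positions are untouched.
#'
#' @param sequence character scalar or [Biostrings::DNAString].
#' @param rate conversion probability per CpG, in \[0,1\].
#' @param seed optional integer; when given the draw is made reproducible
#'   without touching the global RNG stream.
#' @param both_strands when FALSE only the TpG product is created.
#' @return The converted sequence (same type as input) with an integer
#'   attribute `"deaminated"` holding the 0-based positions of the converted
#'   CpG sites (position of the C).
#' @export
deaminate <- function(sequence, rate, seed = NULL, both_strands = TRUE) {
  if (rate < 0 || rate > 1) stop("deaminate: rate must be in [0,1]")
  was_dna <- methods::is(sequence, "DNAString")
  s <- as.character(sequence)
  run <- function() {
    ch <- strsplit(s, NULL)[[1]]
    cg <- which(ch[-length(ch)] == "C" & ch[-1] == "G")
    hit <- cg[stats::runif(length(cg)) < rate]
    if (length(hit)) {
      if (both_strands) {
        to_t <- stats::runif(length(hit)) < 0.5
        ch[hit[to_t]] <- "T"              # CpG -> TpG
        ch[hit[!to_t] + 1L] <- "A"        # CpG -> CpA
      } else {
        ch[hit] <- "T"
      }
    }
    out <- paste(ch, collapse = "")
    attr(out, "deaminated") <- hit - 1L   # 0-based
    out
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (was_dna) {
    pos <- attr(out, "deaminated")
    out <- Biostrings::DNAString(as.character(out))
    attr(out, "deaminated") <- pos
  }
  out
}

## --- internal chromosome builders ------------------------------------------

## segment accumulator: collects sequence chunks and annotation rows
.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$chunks <- list(); env$ann <- list(); env$offset <- 0
  env
}

.add <- function(b, seq, family = NA_character_, repeat_class = NA_character_,
                 divergence = NA_real_) {
  n <- nchar(seq)
  if (n == 0) return(invisible(NULL))
  b$chunks[[length(b$chunks) + 1]] <- seq
  if (!is.na(family)) {
    b$ann[[length(b$ann) + 1]] <- data.frame(
      start = b$offset, end = b$offset + n, family = family,
      repeat_class = repeat_class, divergence = divergence,
      stringsAsFactors = FALSE)
  }
  b$offset <- b$offset + n
  invisible(NULL)
}

## satellite centromere: telomere-proximal SATVII zone (with SINE/LINE/simple
## interruptions), SATII, SATIV, then a SATI/SATVI core whose interspersion
## encodes the structural grammar
.build_satellite_centromere <- function(b, lib, span, grammar) {
  cen_start <- b$offset
  zone <- round(span * c(satvii = 0.15, satii = 0.15, sativ = 0.15, core = 0.55))
  ## SATVII zone interrupted by TE-like and simple repeats
  sv7 <- zone[["satvii"]]
  piece <- round(sv7 / 5)
  .add(b, .tandem(lib$SATVII, piece), "SATVII", "satellite", stats::runif(1, 1, 8))
  .add(b, .mutate(.rand_dna(round(piece / 3)), 0), "SINE_like", "SINE", stats::runif(1, 5, 20))
  .add(b, .tandem(lib$SATVII, piece), "SATVII", "satellite", stats::runif(1, 1, 8))
  .add(b, .mutate(.rand_dna(round(piece / 3)), 0), "LINE_like", "LINE", stats::runif(1, 5, 20))
  .add(b, .tandem(lib$SATVII, piece), "SATVII", "satellite", stats::runif(1, 1, 8))
  .add(b, .tandem("AT", round(piece / 4)), "(AT)n", "simple", 0)
  .add(b, .tandem(lib$SATII, zone[["satii"]]), "SATII", "satellite", stats::runif(1, 1, 8))
  .add(b, .tandem(lib$SATIV, zone[["sativ"]]), "SATIV", "satellite", stats::runif(1, 1, 8))
  core <- zone[["core"]]
  if (grammar == "structure1") {
    blk <- round(core / 6)
    fams <- c("SATI", "SATVI", "SATI", "SATVI", "SATI", "SATVI")
    for (f in fams)
      .add(b, .tandem(lib[[f]], blk), f, "satellite", stats::runif(1, 1, 8))
  } else {
    .add(b, .tandem(lib$SATI, round(core * 0.3)), "SATI", "satellite",
         stats::runif(1, 1, 8))
    .add(b, .tandem(lib$SATVI, round(core * 0.7)), "SATVI", "satellite",
         stats::runif(1, 1, 8))
  }
  c(cen_start, b$offset)
}

## TE-like library for the neocentromere: small fixed set, copies pasted with
## per-copy divergence (emulates remnant TE content without real families)
.te_library <- function() {
  withr::with_seed(24680L, list(TEa = .rand_dna(1500), TEb = .rand_dna(600),
                                TEc = .rand_dna(300)))
}

## Neocentromere: high-identity inverted-repeat pairs embedded in TE-like and
## random filler; all material is template-deaminated at the configured rate
## so the planted pair identity is unaffected by the deamination signature.
.build_neocentromere <- function(b, spec) {
  neo_start <- b$offset
  d <- spec$deamination_rate
  telib <- .te_library()
  pairs <- list()
  mism_rate <- (100 - spec$target_identity) / 200  # per arm
  pair_budget <- spec$n_pairs * (2 * spec$arm_len + 2000)
  filler_total <- max(0, spec$span - pair_budget)
  filler_per_slot <- round(filler_total / (spec$n_pairs + 1))
  deam_positions <- integer()
  add_deaminated <- function(seq, family = NA, class = NA, div = NA) {
    dseq <- deaminate(seq, d)
    pos <- attr(dseq, "deaminated")
    if (length(pos)) deam_positions <<- c(deam_positions, b$offset + pos)
    .add(b, as.character(dseq), family, class, div)
  }
  add_filler <- function(len) {
    remaining <- len
    while (remaining > 0) {
      if (stats::runif(1) < spec$te_fraction) {
        te <- sample(names(telib), 1)
        copy <- .mutate(telib[[te]], stats::runif(1, 0.05, 0.20))
        copy <- substr(copy, 1, min(nchar(copy), remaining))
        add_deaminated(copy, paste0(te, "_like"), "LINE",
                       round(stats::runif(1, 5, 20), 1))
        remaining <- remaining - nchar(copy)
      } else {
        n <- min(remaining, 1000)
        add_deaminated(.rand_dna(n))
        remaining <- remaining - n
      }
    }
  }
  for (k in seq_len(spec$n_pairs)) {
    add_filler(filler_per_slot)
    template <- as.character(deaminate(.rand_dna(spec$arm_len), d))
    left <- .mutate(template, mism_rate)
    right <- .revcomp(.mutate(template, mism_rate))
    spacer <- as.character(deaminate(.rand_dna(2000), d))
    l0 <- b$offset
    .add(b, left)
    .add(b, spacer)
    r0 <- b$offset
    .add(b, right)
    ident <- 100 * mean(strsplit(left, NULL)[[1]] ==
                          strsplit(.revcomp(right), NULL)[[1]])
    pairs[[k]] <- data.frame(left_start = l0, left_end = l0 + nchar(left),
                             right_start = r0, right_end = r0 + nchar(right),
                             percent_identity = ident,
                             spacer_len = r0 - (l0 + nchar(left)))
  }
  add_filler(max(0, spec$span - (b$offset - neo_start)))
  list(interval = c(neo_start, b$offset), pairs = do.call(rbind, pairs),
       deaminated = deam_positions)
}

.build_rdna <- function(b, spec) {
  subunit_seqs <- withr::with_seed(
    13579L, list(`18S` = .rand_dna(spec$len_18s),
                 `5.8S` = .rand_dna(spec$len_5p8s),
                 `28S` = .rand_dna(spec$len_28s)))
  units <- list(); subunits <- list()
  for (u in seq_len(spec$n_units)) {
    u0 <- b$offset
    rows <- list()
    for (nm in c("18S", "5.8S", "28S")) {
      s0 <- b$offset
      .add(b, subunit_seqs[[nm]], paste0("rDNA_", nm), "other", 0)
      rows[[nm]] <- data.frame(subunit = nm, start = s0, end = b$offset)
      if (nm != "28S")
        .add(b, .rand_dna(round(stats::runif(1, spec$spacer_min, spec$spacer_max))))
    }
    units[[u]] <- data.frame(start = u0, end = b$offset, orientation = "+")
    subunits[[u]] <- cbind(unit = u, do.call(rbind, rows))
    .add(b, .rand_dna(round(stats::runif(1, spec$spacer_min, spec$spacer_max))))
  }
  list(units = do.call(rbind, units),
       subunits = do.call(rbind, c(subunits, list(make.row.names = FALSE))),
       subunit_seqs = subunit_seqs)
}

.plant_genes <- function(seq_id, arm_regions, n_genes, id_prefix) {
  rows <- list()
  biotypes <- c("protein_coding", "lncRNA", "rRNA")
  for (g in seq_len(n_genes)) {
    reg <- arm_regions[sample(nrow(arm_regions), 1), ]
    glen <- round(stats::runif(1, 2000, 8000))
    if (reg$end - reg$start < glen + 2) next
    gs <- round(stats::runif(1, reg$start, reg$end - glen))
    ge <- gs + glen
    strand <- sample(c("+", "-"), 1)
    bt <- sample(biotypes, 1, prob = c(0.6, 0.3, 0.1))
    gid <- sprintf("%s_g%03d", id_prefix, g)
    ex1 <- c(gs, gs + round(glen * 0.25))
    ex2 <- c(gs + round(glen * 0.6), ge)
    utr5_len <- 200
    f <- function(type, s, e, id) data.frame(
      seq_id = seq_id, start = s, end = e, strand = strand, type = type,
      source = "sim", feature_id = id, biotype = bt,
      attributes = sprintf("ID=%s;biotype=%s", id, bt),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- do.call(rbind, list(
      f("gene", gs, ge, gid),
      f("exon", ex1[1], ex1[2], paste0(gid, ".e1")),
      f("exon", ex2[1], ex2[2], paste0(gid, ".e2")),
      if (strand == "+") f("five_prime_UTR", gs, gs + utr5_len, paste0(gid, ".u5"))
      else f("five_prime_UTR", ge - utr5_len, ge, paste0(gid, ".u5")),
      if (strand == "+") f("three_prime_UTR", ge - utr5_len, ge, paste0(gid, ".u3"))
      else f("three_prime_UTR", gs, gs + utr5_len, paste0(gid, ".u3"))))
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Simulate a genome with planted centromeres, repeats, rDNA and SV truth
#'
#' Acrocentric chromosomes carry a satellite centromere downstream of the
#' p-arm telomere whose family order follows the canonical grammar (telomere,
#' SATVII with SINE/LINE/simple interruptions, SATII, SATIV, then a SATI/SATVI
#' core whose interspersion encodes structure 1 vs structure 2). The last
#' chromosome (id `chrX`) instead carries a satellite-free neocentromere of
#' TE-like repeats and high-identity inverted-repeat pairs, CpG-deaminated at
#' the configured rate. The first chromosome carries a tandem rDNA array
#' (ordered 18S/5.8S/28S blocks with variable spacers) on its q arm.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `genome` ([Biostrings::DNAStringSet]),
#'   `repeats` (RepeatMasker-style annotation data.frame), `genes`
#'   (GFF3-style data.frame) and `truth` (ground-truth list: `centromeres`,
#'   `telomeres`, `gaps`, `inverted_pairs`, `rdna`, `svs`, `deaminated`,
#'   `methylation_regions`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_genome_impl(config))
}

.simulate_genome_impl <- function(config) {
  lib <- config$satellite_library
  n_chr <- config$n_chromosomes
  has_x <- config$x_chromosome && n_chr >= 1
  n_auto <- n_chr - as.integer(has_x)
  chrom_ids <- c(sprintf("chr%d", seq_len(n_auto)), if (has_x) "chrX")
  grammars <- rep_len(config$centromere_grammar, max(n_auto, 1))
  seqs <- character(n_chr); names(seqs) <- chrom_ids
  repeats <- list(); genes <- list()
  truth <- list(centromeres = list(), telomeres = list(), gaps = list(),
                inverted_pairs = NULL, rdna = NULL, deaminated = list())
  tel_len <- rep_len(config$telomere_tract_len, n_chr)
  L <- rep_len(config$chrom_length, n_chr)

  for (i in seq_len(n_chr)) {
    id <- chrom_ids[i]
    is_x <- has_x && i == n_chr
    b <- .new_builder()
    ## p telomere (C-strand repeats on the forward strand at the p end)
    if (tel_len[i] > 0)
      .add(b, .tandem(.revcomp(config$telomere_unit), tel_len[i]),
           "telomere", "simple", 0)
    p_tel_end <- b$offset
    if (!is_x) {
      .add(b, .rand_dna(10000))   # short pericentric p-arm gap sequence
      cen <- .build_satellite_centromere(b, lib, config$centromere_span,
                                         grammars[i])
      truth$centromeres[[id]] <- data.frame(
        seq_id = id, start = cen[1], end = cen[2], structure = grammars[i],
        stringsAsFactors = FALSE)
      ## q arm, leaving room for rDNA on chr1 and the q telomere
      rdna_here <- (i == 1 && config$rdna_spec$n_units > 0)
      arm_target <- L[i] - b$offset - tel_len[i] -
        if (rdna_here) config$rdna_spec$n_units *
          (config$rdna_spec$len_18s + config$rdna_spec$len_5p8s +
             config$rdna_spec$len_28s + 3 * config$rdna_spec$spacer_max) else 0
      q_arm_start <- b$offset
      .add(b, .rand_dna(max(0, round(arm_target))))
      if (rdna_here) {
        rd <- .build_rdna(b, config$rdna_spec)
        rd$units <- cbind(seq_id = id, rd$units)
        rd$subunits <- cbind(seq_id = id, rd$subunits)
        truth$rdna <- rd
      }
      arm_regions <- data.frame(start = c(q_arm_start),
                                end = c(q_arm_start + max(1000, arm_target)))
    } else {
      ## X-like: long p arm, neocentromere near the middle, long q arm
      p_arm <- round((L[i] - config$neocentromere_spec$span) / 2) - b$offset
      p_arm_start <- b$offset
      .add(b, .rand_dna(max(0, p_arm)))
      neo <- .build_neocentromere(b, config$neocentromere_spec)
      truth$centromeres[[id]] <- data.frame(
        seq_id = id, start = neo$interval[1], end = neo$interval[2],
        structure = "neocentromere_like", stringsAsFactors = FALSE)
      truth$inverted_pairs <- cbind(seq_id = id, neo$pairs)
      truth$deaminated[[id]] <- neo$deaminated
      q_arm_start <- b$offset
      .add(b, .rand_dna(max(0, L[i] - b$offset - tel_len[i])))
      arm_regions <- data.frame(start = c(p_arm_start, q_arm_start),
                                end = c(p_arm_start + max(1000, p_arm),
                                        max(q_arm_start + 1000, L[i] - tel_len[i])))
    }
    if (tel_len[i] > 0)
      .add(b, .tandem(config$telomere_unit, tel_len[i]), "telomere", "simple", 0)
    seq <- paste(unlist(b$chunks), collapse = "")
    truth$telomeres[[id]] <- data.frame(
      seq_id = id,
      p_start = 0, p_end = if (tel_len[i] > 0) p_tel_end else 0,
      q_start = if (tel_len[i] > 0) nchar(seq) - tel_len[i] else nchar(seq),
      q_end = nchar(seq), stringsAsFactors = FALSE)
    ann <- if (length(b$ann)) do.call(rbind, b$ann) else NULL
    if (!is.null(ann)) repeats[[id]] <- cbind(seq_id = id, ann)
    g <- .plant_genes(id, arm_regions, config$n_genes, id)
    if (!is.null(g)) genes[[id]] <- g
    seqs[i] <- seq
  }

  ## N-gaps requested in the config are burned into the sequence
  gap_rows <- list()
  for (gap in config$gap_spec) {
    s <- seqs[[gap$chrom]]
    if (gap$position + gap$length > nchar(s))
      stop("gap_spec: gap exceeds chromosome length on ", gap$chrom)
    substr(s, gap$position + 1, gap$position + gap$length) <-
      strrep("N", gap$length)
    seqs[[gap$chrom]] <- s
    gap_rows[[length(gap_rows) + 1]] <- data.frame(
      seq_id = gap$chrom, start = gap$position,
      end = gap$position + gap$length, stringsAsFactors = FALSE)
  }
  truth$gaps <- if (length(gap_rows)) do.call(rbind, gap_rows) else
    data.frame(seq_id = character(), start = numeric(), end = numeric())

  truth$centromeres <- do.call(rbind, truth$centromeres)
  truth$telomeres <- do.call(rbind, truth$telomeres)
  truth$svs <- .simulate_sv_truth(chrom_ids, vapply(seqs, nchar, 1),
                                  config$sv_spec)
  genome <- Biostrings::DNAStringSet(seqs)
  list(genome = genome,
       repeats = do.call(rbind, c(repeats, list(make.row.names = FALSE))),
       genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
       truth = truth)
}

.simulate_sv_truth <- function(chrom_ids, chrom_lens, spec) {
  n_total <- sum(spec$n_sv)
  if (n_total == 0)
    return(list(table = NULL, genotypes = NULL))
  types <- rep(names(spec$n_sv), spec$n_sv)
  chrom <- sample(chrom_ids, n_total, replace = TRUE)
  len <- round(exp(stats::runif(n_total, log(spec$min_len), log(spec$max_len))))
  start <- vapply(seq_len(n_total), function(k)
    round(stats::runif(1, 1000, chrom_lens[chrom[k]] - max(len[k], 1) - 1000)), 1)
  tab <- data.frame(sv_id = sprintf("sv%04d", seq_len(n_total)),
                    seq_id = chrom, start = start,
                    end = ifelse(types == "INS", start + 1, start + len),
                    sv_type = types, length = len, stringsAsFactors = FALSE)
  samples <- sprintf("S%02d", seq_len(spec$n_samples))
  alleles <- matrix(stats::rbinom(n_total * spec$n_samples * 2, 1,
                                  spec$allele_freq),
                    nrow = n_total * spec$n_samples)
  gt <- matrix(c("0/0", "0/1", "1/1")[alleles[, 1] + alleles[, 2] + 1],
               nrow = n_total, dimnames = list(tab$sv_id, samples))
  ## guarantee each SV is carried by at least two samples so the
  ## high-confidence filter is attainable at full sensitivity
  for (k in seq_len(n_total)) {
    carriers <- sum(gt[k, ] != "0/0")
    if (carriers < 2) {
      fix <- sample(spec$n_samples, 2 - carriers)
      gt[k, fix] <- "0/1"
    }
  }
  list(table = tab, genotypes = gt)
}

#' Simulate per-caller, per-sample SV callsets from planted truth
#'
#' Each true SV carried by a sample (genotype not 0/0) is reported by each
#' caller with the configured sensitivity, with breakpoint jitter up to
#' `pos_jitter` and genotype discordance at `genotype_error`. False calls are
#' added per caller/sample as a Poisson draw with mean
#' `false_rate * n_true_calls`.
#'
#' @param truth the `svs` element of [simulate_genome()] truth (or a
#'   compatible `list(table=, genotypes=)`).
#' @param sv_spec the `sv_spec` list from [sim_config()].
#' @param seed integer seed.
#' @param chrom_lens named lengths used to place false calls; defaults to the
#'   max coordinate seen per chromosome plus margin.
#' @return data.frame of calls: `seq_id,start,end,sv_type,length,caller,sample,genotype`.
#' @export
simulate_sv_callsets <- function(truth, sv_spec, seed, chrom_lens = NULL) {
  withr::with_seed(seed, {
    tab <- truth$table; gt <- truth$genotypes
    if (is.null(tab) || nrow(tab) == 0)
      return(data.frame(seq_id = character(), start = numeric(),
                        end = numeric(), sv_type = character(),
                        length = numeric(), caller = character(),
                        sample = character(), genotype = character()))
    if (is.null(chrom_lens)) {
      chrom_lens <- tapply(tab$end, tab$seq_id, max) + 1e5
    }
    samples <- colnames(gt)
    out <- list()
    for (caller in sv_spec$callers) {
      for (s in samples) {
        carried <- which(gt[, s] != "0/0")
        det <- carried[stats::runif(length(carried)) < sv_spec$sensitivity]
        if (length(det)) {
          jit <- round(stats::runif(length(det), -sv_spec$pos_jitter,
                                    sv_spec$pos_jitter))
          g <- gt[det, s]
          flip <- stats::runif(length(det)) < sv_spec$genotype_error
          g[flip] <- ifelse(g[flip] == "0/1", "1/1", "0/1")
          st <- pmax(0, tab$start[det] + jit)
          out[[length(out) + 1]] <- data.frame(
            seq_id = tab$seq_id[det], start = st,
            end = ifelse(tab$sv_type[det] == "INS", st + 1,
                         st + tab$length[det]),
            sv_type = tab$sv_type[det], length = tab$length[det],
            caller = caller, sample = s, genotype = g,
            stringsAsFactors = FALSE)
        }
        n_false <- stats::rpois(1, sv_spec$false_rate * length(carried))
        if (n_false > 0) {
          fc <- sample(names(chrom_lens), n_false, replace = TRUE)
          fl <- round(exp(stats::runif(n_false, log(sv_spec$min_len),
                                       log(sv_spec$max_len))))
          fs <- vapply(seq_len(n_false), function(k)
            round(stats::runif(1, 0, max(1, chrom_lens[fc[k]] - fl[k]))), 1)
          ft <- sample(unique(tab$sv_type), n_false, replace = TRUE)
          out[[length(out) + 1]] <- data.frame(
            seq_id = fc, start = fs,
            end = ifelse(ft == "INS", fs + 1, fs + fl),
            sv_type = ft, length = fl, caller = caller, sample = s,
            genotype = sample(c("0/1", "1/1"), n_false, replace = TRUE),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(out))
      return(data.frame(seq_id = character(), start = numeric(),
                        end = numeric(), sv_type = character(),
                        length = numeric(), caller = character(),
                        sample = character(), genotype = character()))
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    res[order(res$seq_id, res$start), , drop = FALSE]
  })
}

#' Simulate per-CpG methylation records
#'
#' One record per CpG site per platform. Methylated fraction is drawn from a
#' Beta distribution with a region-specific mean (centromere vs arm) and the
#' configured precision; coverage is Poisson. The two platforms (ONT, PacBio)
#' get independent noise around the same regional means.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param truth truth list with a `centromeres` data.frame (may be NULL for
#'   all-arm genomes).
#' @param methylation_spec list with `mean_arm`, `mean_centromere`,
#'   `dispersion`, `mean_coverage`.
#' @param seed integer seed.
#' @param platforms character vector of platform labels.
#' @return data.frame `seq_id,start,end,coverage,meth_fraction,platform`.
#' @export
simulate_methylation <- function(genome, truth, methylation_spec, seed,
                                 platforms = c("ONT", "PacBio")) {
  spec <- methylation_spec
  withr::with_seed(seed, {
    out <- list()
    for (id in names(genome)) {
      cg <- Biostrings::start(Biostrings::matchPattern("CG", genome[[id]])) - 1L
      if (length(cg) == 0) next
      cen <- truth$centromeres
      in_cen <- rep(FALSE, length(cg))
      if (!is.null(cen)) {
        cr <- cen[cen$seq_id == id, , drop = FALSE]
        for (j in seq_len(nrow(cr)))
          in_cen <- in_cen | (cg >= cr$start[j] & cg < cr$end[j])
      }
      mu <- ifelse(in_cen, spec$mean_centromere, spec$mean_arm)
      for (pf in platforms) {
        disp <- spec$dispersion
        meth <- if (is.finite(disp) && disp > 0)
          stats::rbeta(length(cg), mu * disp, (1 - mu) * disp)
        else mu
        out[[length(out) + 1]] <- data.frame(
          seq_id = id, start = cg, end = cg + 2L,
          coverage = stats::rpois(length(cg), spec$mean_coverage) + 1L,
          meth_fraction = meth, platform = pf, stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) {
      warning("no CpG sites in genome; empty methylation output")
      return(data.frame(seq_id = character(), start = numeric(),
                        end = numeric(), coverage = numeric(),
                        meth_fraction = numeric(), platform = character()))
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Simulate CENP-A-style peak calls over repeat annotations
#'
#' Peaks are placed inside annotated repeat intervals, with one family
#' receiving `enrich_factor` times the baseline per-kb peak density and score.
#'
#' @param repeats annotation data.frame (`seq_id,start,end,family`).
#' @param enrich_family family to enrich (NULL for uniform density).
#' @param peaks_per_kb baseline expected peaks per kb of repeat sequence.
#' @param enrich_factor density/score multiplier for the enriched family.
#' @param seed integer seed.
#' @return data.frame of peaks `seq_id,start,end,score`.
#' @export
simulate_cenpa_peaks <- function(repeats, enrich_family = NULL,
                                 peaks_per_kb = 0.2, enrich_factor = 5,
                                 seed = 1L) {
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(repeats))) {
      w <- repeats$end[i] - repeats$start[i]
      rate <- peaks_per_kb * w / 1000
      boost <- !is.null(enrich_family) && repeats$family[i] == enrich_family
      if (boost) rate <- rate * enrich_factor
      n <- stats::rpois(1, rate)
      if (n == 0) next
      ps <- round(stats::runif(n, repeats$start[i], max(repeats$start[i],
                                                        repeats$end[i] - 200)))
      out[[length(out) + 1]] <- data.frame(
        seq_id = repeats$seq_id[i], start = ps, end = ps + 200,
        score = stats::rgamma(n, shape = 5, rate = if (boost) 1 / enrich_factor else 1),
        stringsAsFactors = FALSE)
    }
    if (!length(out))
      return(data.frame(seq_id = character(), start = numeric(),
                        end = numeric(), score = numeric()))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Generate BLAST-style subunit hits from planted rDNA truth
#'
#' Produces one alignment hit per planted subunit at the requested identity
#' and query coverage, suitable as input to [detect_rdna_units()].
#'
#' @param rdna the `rdna` truth element of [simulate_genome()] (needs the
#'   `subunits` data.frame).
#' @param identity reported percent identity (scalar or per-hit).
#' @param query_coverage reported query coverage fraction.
#' @param evalue reported e-value.
#' @return AlignmentHit data.frame compatible with `read_annotations(...,
#'   "blast_tab")` output.
#' @export
rdna_hits_from_truth <- function(rdna, identity = 99, query_coverage = 0.98,
                                 evalue = 1e-50) {
  su <- rdna$subunits
  if (is.null(su) || nrow(su) == 0)
    return(data.frame(query_id = character(), seq_id = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), percent_identity = numeric(),
                      aln_length = numeric(), mismatch = numeric(),
                      gapopen = numeric(), qstart = numeric(),
                      qend = numeric(), evalue = numeric(),
                      bitscore = numeric(), query_coverage = numeric()))
  data.frame(query_id = su$subunit, seq_id = su$seq_id, start = su$start,
             end = su$end, strand = "+",
             percent_identity = rep_len(identity, nrow(su)),
             aln_length = su$end - su$start, mismatch = 0, gapopen = 0,
             qstart = 1, qend = su$end - su$start,
             evalue = rep_len(evalue, nrow(su)), bitscore = 1000,
             query_coverage = rep_len(query_coverage, nrow(su)),
             stringsAsFactors = FALSE)
}

#' Write a simulated genome and its ground truth to disk
#'
#' Writes FASTA, a repeat BED (name = family), a GFF3 gene file and the truth
#' as JSON.
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             repeats = file.path(dir, "repeats.bed"),
             genes = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.json"))
  write_fasta(sim$genome, paths["fasta"])
  rep_bed <- data.frame(seq_id = sim$repeats$seq_id, start = sim$repeats$start,
                        end = sim$repeats$end, name = sim$repeats$family,
                        score = 0, strand = "+")
  write_bed(rep_bed, paths["repeats"])
  g <- sim$genes
  gff <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", g$seq_id, g$source,
                 g$type, as.integer(g$start + 1), as.integer(g$end),
                 g$strand, g$attributes)
  writeLines(c("##gff-version 3", gff), paths["genes"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
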