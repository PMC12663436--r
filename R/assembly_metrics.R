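#' Split scaffolds into contigs at N-gaps
#'
#' Gaps are maximal runs of at least `min_gap_run` consecutive N. Contigs are
#' the non-N segments between them; terminal N-runs produce no empty contigs.
#'
#' @param genome [Biostrings::DNAStringSet] (or named character vector).
#' @param min_gap_run minimum N-run length that counts as a gap; the default
#'   of 1 makes every N-run split its scaffold once, which keeps the identity
#'   `n_contigs == n_scaffolds + n_gaps` exact.
#' @return list with `contigs` (data.frame `seq_id,start,end,length`) and
#'   `gaps` (data.frame `seq_id,start,end`).
#' @export
split_contigs <- function(genome, min_gap_run = 1L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  contigs <- list(); gaps <- list()
  for (id in names(genome)) {
    s <- as.character(genome[[id]])
    L <- nchar(s)
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1) {
      runs <- data.frame(start = numeric(0), end = numeric(0))
    } else {
      st <- as.numeric(m) - 1
      en <- st + attr(m, "match.length")
      keep <- (en - st) >= min_gap_run
      runs <- data.frame(start = st[keep], end = en[keep])
    }
    if (nrow(runs))
      gaps[[length(gaps) + 1]] <- cbind(seq_id = id, runs)
    bounds <- c(0, as.vector(t(as.matrix(runs))), L)
    cs <- bounds[seq(1, length(bounds), by = 2)]
    ce <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ce > cs
    if (any(keep))
      contigs[[length(contigs) + 1]] <- data.frame(
        seq_id = id, start = cs[keep], end = ce[keep],
        length = ce[keep] - cs[keep], stringsAsFactors = FALSE)
  }
  list(contigs = if (length(contigs)) do.call(rbind, contigs) else
         data.frame(seq_id = character(), start = numeric(),
                    end = numeric(), length = numeric()),
       gaps = if (length(gaps)) do.call(rbind, gaps) else
         data.frame(seq_id = character(), start = numeric(), end = numeric()))
}

#' Nx assembly statistic
#'
#' The smallest length L such that sequences of length >= L together contain
#' at least x% of the total bases (N50 when `x = 50`).
#'
#' @param lengths positive sequence lengths.
#' @param x percentage threshold.
#' @return length in bp.
#' @export
nx_stat <- function(lengths, x = 50) {
  if (length(lengths) == 0) stop("nx_stat: empty length set")
  if (any(lengths <= 0)) stop("nx_stat: lengths must be positive")
  sorted <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(sorted)
  sorted[which(cum >= x / 100 * sum(sorted))[1]]
}

## 0/1 mask of positions covered by the unit or its reverse complement
.telomere_mask <- function(seq_dna, unit) {
  L <- length(seq_dna)
  mask <- logical(L)
  for (u in c(unit, .revcomp(unit))) {
    m <- Biostrings::matchPattern(u, seq_dna)
    if (length(m))
      for (k in seq_along(m)) {
        mask[Biostrings::start(m)[k]:Biostrings::end(m)[k]] <- TRUE
      }
  }
  mask
}

#' Detect a telomeric tract at a chromosome terminus
#'
#' Scans consecutive windows from the given terminus; a tract is the maximal
#' run of windows whose telomeric-unit base density (unit and reverse
#' complement both counted) is at least `min_density`. The tract must begin
#' within `terminus_slack` bp of the terminus and span at least `min_tract`
#' bp.
#'
#' @param sequence a [Biostrings::DNAString] or character scalar.
#' @param terminus `"p"` (sequence start) or `"q"` (sequence end).
#' @param unit telomeric repeat unit.
#' @param window scan window in bp.
#' @param min_density minimum telomeric base density per window.
#' @param min_tract minimum tract span in bp.
#' @param terminus_slack maximum distance of the tract start from the
#'   terminus.
#' @return list (`start,end,unit_count,density,terminus`) or NULL when no
#'   tract qualifies.
#' @export
detect_telomere_tract <- function(sequence, terminus = c("p", "q"),
                                  unit = "TTAGGG", window = 100L,
                                  min_density = 0.8, min_tract = 200L,
                                  terminus_slack = 1000L) {
  terminus <- match.arg(terminus)
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  L <- length(sequence)
  ## only the terminal stretch can matter
  scan_len <- min(L, max(terminus_slack + 10 * min_tract, 100000L))
  if (terminus == "p") {
    sub <- Biostrings::subseq(sequence, 1, scan_len)
    mask <- .telomere_mask(sub, unit)
  } else {
    sub <- Biostrings::subseq(sequence, L - scan_len + 1, L)
    mask <- rev(.telomere_mask(sub, unit))
  }
  ## mask is now oriented terminus-first
  n_win <- floor(length(mask) / window)
  if (n_win == 0) return(NULL)
  dens <- vapply(seq_len(n_win), function(k)
    mean(mask[((k - 1) * window + 1):(k * window)]), numeric(1))
  ok <- dens >= min_density
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  cand <- which(r$values & (run_start - 1) * window <= terminus_slack)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  off0 <- (run_start[best] - 1) * window
  off1 <- run_end[best] * window
  if (off1 - off0 < min_tract) return(NULL)
  tract_mask <- mask[(off0 + 1):off1]
  ## convert terminus-relative offsets to forward coordinates (0-based)
  if (terminus == "p") {
    start <- off0; end <- off1
  } else {
    start <- L - off1; end <- L - off0
  }
  tract_seq <- Biostrings::subseq(sequence, start + 1, end)
  cnt <- function(u, s) {
    g <- gregexpr(u, s, fixed = TRUE)[[1]]
    if (g[1] == -1) 0L else length(g)
  }
  uc <- cnt(unit, as.character(tract_seq)) +
    cnt(.revcomp(unit), as.character(tract_seq))
  list(start = start, end = end, unit_count = uc,
       density = mean(tract_mask), terminus = terminus)
}

#' Count telomere units genome-wide
#'
#' Non-overlapping exact occurrences of the unit plus its reverse complement,
#' summed over all sequences.
#'
#' @param sequences [Biostrings::DNAStringSet] or character vector.
#' @param unit telomeric repeat unit.
#' @return integer count.
#' @export
count_telomere_units <- function(sequences, unit = "TTAGGG") {
  s <- as.character(sequences)
  cnt <- function(u, x) {
    g <- gregexpr(u, x, fixed = TRUE)[[1]]
    if (g[1] == -1) 0L else length(g)
  }
  sum(vapply(s, function(x) cnt(unit, x) + cnt(.revcomp(unit), x),
             integer(1)))
}

#' Classify a chromosome's telomere-to-telomere status
#'
#' T2T: telomeric tracts at both termini and zero gaps. TgapT: tracts at both
#' termini but internal gaps remain. partial: tract at exactly one terminus.
#' none: no tract at either terminus.
#'
#' @param has_p,has_q logical; telomere tract detected at the p / q terminus.
#' @param n_gaps number of N-gaps in the chromosome.
#' @return one of `"T2T"`, `"TgapT"`, `"partial"`, `"none"`.
#' @export
classify_t2t <- function(has_p, has_q, n_gaps) {
  if (has_p && has_q) {
    if (n_gaps == 0) "T2T" else "TgapT"
  } else if (has_p || has_q) "partial" else "none"
}

#' Whole-assembly completeness statistics
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param min_gap_run minimum N-run length that counts as a gap.
#' @param telomere_unit telomeric repeat unit.
#' @param ... further arguments to [detect_telomere_tract()].
#' @return list: `total_bp`, `n_scaffolds`, `n_contigs`, `n_gaps`,
#'   `contig_n50`, `scaffold_n50`, `telomere_units`, and a per-chromosome
#'   data.frame `chromosomes` with telomere status and T2T class.
#' @export
assembly_stats <- function(genome, min_gap_run = 1L, telomere_unit = "TTAGGG",
                           ...) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  sc <- split_contigs(genome, min_gap_run = min_gap_run)
  lens <- Biostrings::width(genome)
  per_chrom <- lapply(names(genome), function(id) {
    p <- detect_telomere_tract(genome[[id]], "p", unit = telomere_unit, ...)
    q <- detect_telomere_tract(genome[[id]], "q", unit = telomere_unit, ...)
    ng <- sum(sc$gaps$seq_id == id)
    status <- if (!is.null(p) && !is.null(q)) "both_ends"
      else if (!is.null(p)) "p_only" else if (!is.null(q)) "q_only" else "none"
    data.frame(seq_id = id, length = nchar(as.character(genome[[id]])),
               n_gaps = ng, telomere_status = status,
               t2t_class = classify_t2t(!is.null(p), !is.null(q), ng),
               p_tract_len = if (is.null(p)) 0 else p$end - p$start,
               q_tract_len = if (is.null(q)) 0 else q$end - q$start,
               stringsAsFactors = FALSE)
  })
  per_chrom <- do.call(rbind, per_chrom)
  list(total_bp = sum(lens),
       n_scaffolds = length(genome),
       n_contigs = nrow(sc$contigs),
       n_gaps = nrow(sc$gaps),
       contig_n50 = nx_stat(sc$contigs$length),
       scaffold_n50 = nx_stat(lens),
       telomere_units = count_telomere_units(genome, telomere_unit),
       chromosomes = per_chrom,
       gaps = sc$gaps)
}
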