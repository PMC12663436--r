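#' Read genome sequences from FASTA
#'
#' Sequences are uppercased and IUPAC ambiguity codes other than N are mapped
#' to N (a message reports how many bases were converted). Record IDs are the
#' first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file (plain or line-wrapped).
#' @return A [Biostrings::DNAStringSet] over the alphabet `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA in ", path, ": ",
                                            conditionMessage(e)))
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  raw <- toupper(as.character(seqs))
  empty <- nchar(raw) == 0
  if (any(empty))
    stop("empty sequence for FASTA record(s): ",
         paste(ids[empty], collapse = ", "))
  clean <- gsub("[^ACGTN]", "N", raw)
  n_mapped <- sum(vapply(seq_along(raw), function(i) {
    sum(charToRaw(raw[i]) != charToRaw(clean[i]))
  }, integer(1)))
  if (n_mapped > 0)
    message(n_mapped, " ambiguous base(s) mapped to N")
  out <- Biostrings::DNAStringSet(clean)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

.rm_class_map <- function(cls) {
  top <- sub("/.*$", "", cls)
  out <- rep("other", length(cls))
  out[top == "Satellite"] <- "satellite"
  out[top == "SINE"] <- "SINE"
  out[top == "LINE"] <- "LINE"
  out[top == "LTR"] <- "LTR"
  out[top %in% c("Simple_repeat", "Low_complexity")] <- "simple"
  out
}

.parse_fail <- function(path, i, what) {
  stop(sprintf("%s: unparseable %s line %d", path, what, i))
}

#' Read annotation files into typed interval tables
#'
#' All dialects are normalized to the package's 0-based half-open coordinate
#' convention: BED and bedMethyl are taken as-is; GFF3, RepeatMasker `.out` and
#' BLAST subject coordinates are converted from 1-based inclusive. BLAST hits
#' with subject start > end are flagged strand `"-"` and their coordinates
#' swapped.
#'
#' Dialects and their output columns:
#' \describe{
#'   \item{bed}{`seq_id,start,end,name,score,strand`}
#'   \item{gff3}{`seq_id,start,end,strand,type,source,feature_id,biotype,attributes`}
#'   \item{repeatmasker_out}{`seq_id,start,end,strand,family,repeat_class,divergence,overlapping`}
#'   \item{irf_ngs}{`seq_id,left_start,left_end,right_start,right_end,percent_identity,spacer_len`
#'     (header lines beginning `@` carry the sequence id)}
#'   \item{blast_tab}{outfmt-6 columns with the subject interval normalized:
#'     `query_id,seq_id,start,end,strand,percent_identity,aln_length,mismatch,gapopen,qstart,qend,evalue,bitscore,query_coverage`}
#'   \item{bedmethyl}{modkit-style: `seq_id,start,end,strand,coverage,meth_fraction`
#'     (percent methylated divided by 100 on read)}
#' }
#'
#' @param path input file.
#' @param dialect one of `bed`, `gff3`, `repeatmasker_out`, `irf_ngs`,
#'   `blast_tab`, `bedmethyl`.
#' @return A data.frame; rejected rows (none are dropped silently) are
#'   reported in the `"rejected"` attribute with reasons.
#' @export
read_annotations <- function(path, dialect = c("bed", "gff3",
                                               "repeatmasker_out", "irf_ngs",
                                               "blast_tab", "bedmethyl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  switch(dialect,
         bed = .read_bed(lines, path),
         gff3 = .read_gff3(lines, path),
         repeatmasker_out = .read_rm_out(lines, path),
         irf_ngs = .read_irf(lines, path),
         blast_tab = .read_blast(lines, path),
         bedmethyl = .read_bedmethyl(lines, path))
}

.read_bed <- function(lines, path) {
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  rows <- strsplit(lines[keep], "\t")
  idx <- which(keep)
  n <- vapply(rows, length, integer(1))
  bad <- n < 3
  for (i in which(bad)) .parse_fail(path, idx[i], "BED")
  df <- data.frame(
    seq_id = vapply(rows, `[`, "", 1),
    start = suppressWarnings(as.numeric(vapply(rows, `[`, "", 2))),
    end = suppressWarnings(as.numeric(vapply(rows, `[`, "", 3))),
    name = vapply(rows, function(r) if (length(r) >= 4) r[4] else NA_character_, ""),
    score = suppressWarnings(as.numeric(
      vapply(rows, function(r) if (length(r) >= 5) r[5] else NA_character_, ""))),
    strand = vapply(rows, function(r) if (length(r) >= 6) r[6] else ".", ""),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    .parse_fail(path, idx[which(is.na(df$start) | is.na(df$end))[1]], "BED")
  attr(df, "rejected") <- data.frame(line = integer(), reason = character())
  df
}

.read_gff3 <- function(lines, path) {
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- strsplit(lines[keep], "\t")
  idx <- which(keep)
  for (i in seq_along(rows))
    if (length(rows[[i]]) < 9) .parse_fail(path, idx[i], "GFF3")
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  attrs <- vapply(rows, `[`, "", 9)
  df <- data.frame(
    seq_id = vapply(rows, `[`, "", 1),
    start = as.numeric(vapply(rows, `[`, "", 4)) - 1,
    end = as.numeric(vapply(rows, `[`, "", 5)),
    strand = vapply(rows, `[`, "", 7),
    type = vapply(rows, `[`, "", 3),
    source = vapply(rows, `[`, "", 2),
    feature_id = attr_field(attrs, "ID"),
    biotype = attr_field(attrs, "biotype"),
    attributes = attrs,
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    .parse_fail(path, idx[which(is.na(df$start) | is.na(df$end))[1]], "GFF3")
  attr(df, "rejected") <- data.frame(line = integer(), reason = character())
  df
}

.read_rm_out <- function(lines, path) {
  ## RepeatMasker .out: two header lines + blank, then whitespace-separated
  ## rows; a trailing "*" marks a row overlapping a higher-scoring match.
  body <- lines[nzchar(trimws(lines))]
  body <- body[!grepl("^\\s*(SW|score)\\b", body)]
  rows <- strsplit(trimws(body), "\\s+")
  for (i in seq_along(rows))
    if (length(rows[[i]]) < 14) .parse_fail(path, i, "RepeatMasker .out")
  strand_raw <- vapply(rows, `[`, "", 9)
  df <- data.frame(
    seq_id = vapply(rows, `[`, "", 5),
    start = as.numeric(vapply(rows, `[`, "", 6)) - 1,
    end = as.numeric(vapply(rows, `[`, "", 7)),
    strand = ifelse(strand_raw == "C", "-", "+"),
    family = vapply(rows, `[`, "", 10),
    repeat_class = .rm_class_map(vapply(rows, `[`, "", 11)),
    divergence = as.numeric(vapply(rows, `[`, "", 2)),
    overlapping = vapply(rows, function(r) r[length(r)] == "*", logical(1)),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$divergence))
    .parse_fail(path, which(is.na(df$start) | is.na(df$end))[1],
                "RepeatMasker .out")
  attr(df, "rejected") <- data.frame(line = integer(), reason = character())
  df
}

.read_irf <- function(lines, path) {
  seq_id <- NA_character_
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "@")) {
      seq_id <- sub("^@\\s*", "", ln)
      seq_id <- sub("\\s.*$", "", seq_id)
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 5) .parse_fail(path, i, "IRF -ngs")
    v <- suppressWarnings(as.numeric(f[1:5]))
    if (anyNA(v)) .parse_fail(path, i, "IRF -ngs")
    if (is.na(seq_id)) stop(path, ": IRF data row before any @sequence header (line ", i, ")")
    ## columns: left start, left end, right start, right end (1-based
    ## inclusive), percent identity
    out[[length(out) + 1]] <- data.frame(
      seq_id = seq_id, left_start = v[1] - 1, left_end = v[2],
      right_start = v[3] - 1, right_end = v[4], percent_identity = v[5],
      stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(), left_start = numeric(),
               left_end = numeric(), right_start = numeric(),
               right_end = numeric(), percent_identity = numeric())
  df$spacer_len <- df$right_start - df$left_end
  attr(df, "rejected") <- data.frame(line = integer(), reason = character())
  df
}

.read_blast <- function(lines, path) {
  keep <- nzchar(lines) & !grepl("^#", lines)
  rows <- strsplit(lines[keep], "\t")
  idx <- which(keep)
  for (i in seq_along(rows))
    if (length(rows[[i]]) < 12) .parse_fail(path, idx[i], "BLAST tabular")
  num <- function(k) suppressWarnings(as.numeric(vapply(rows, `[`, "", k)))
  sstart <- num(9); send <- num(10)
  minus <- sstart > send
  df <- data.frame(
    query_id = vapply(rows, `[`, "", 1),
    seq_id = vapply(rows, `[`, "", 2),
    start = ifelse(minus, send, sstart) - 1,
    end = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    percent_identity = num(3),
    aln_length = num(4),
    mismatch = num(5),
    gapopen = num(6),
    qstart = num(7),
    qend = num(8),
    evalue = num(11),
    bitscore = num(12),
    query_coverage = if (any(vapply(rows, length, 1L) >= 13))
      suppressWarnings(as.numeric(vapply(rows, function(r)
        if (length(r) >= 13) r[13] else NA_character_, ""))) / 100
      else NA_real_,
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$percent_identity))
    .parse_fail(path, idx[which(is.na(df$start))[1]], "BLAST tabular")
  attr(df, "rejected") <- data.frame(line = integer(), reason = character())
  df
}

.read_bedmethyl <- function(lines, path) {
  keep <- nzchar(lines) & !grepl("^#", lines)
  rows <- strsplit(lines[keep], "\t")
  idx <- which(keep)
  for (i in seq_along(rows))
    if (length(rows[[i]]) < 11) .parse_fail(path, idx[i], "bedMethyl")
  num <- function(k) suppressWarnings(as.numeric(vapply(rows, `[`, "", k)))
  df <- data.frame(
    seq_id = vapply(rows, `[`, "", 1),
    start = num(2),
    end = num(3),
    strand = vapply(rows, `[`, "", 6),
    coverage = num(10),
    meth_fraction = num(11) / 100,
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$meth_fraction) ||
      any(df$meth_fraction < 0 | df$meth_fraction > 1) ||
      any(df$coverage < 0))
    .parse_fail(path, idx[1], "bedMethyl")
  attr(df, "rejected") <- data.frame(line = integer(), reason = character())
  df
}

#' Write an interval table as BED
#' @param intervals data.frame with `seq_id,start,end` and optional
#'   `name,score,strand`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(intervals$seq_id, format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   if (!is.null(intervals$name)) intervals$name else ".",
                   if (!is.null(intervals$score)) intervals$score else 0,
                   if (!is.null(intervals$strand)) intervals$strand else ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
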