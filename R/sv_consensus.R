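#' Read a minimal SV call table
#'
#' Tab-separated columns: `chrom, start, end, type, length, caller, sample,
#' genotype` (header optional; detected by a non-numeric second field of the
#' first line).
#'
#' @param path input TSV.
#' @return data.frame `seq_id,start,end,sv_type,length,caller,sample,genotype`.
#' @export
read_sv_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  names(df) <- c("seq_id", "start", "end", "sv_type", "length", "caller",
                 "sample", "genotype")[seq_len(ncol(df))]
  df
}

#' Merge SV calls across callers and samples
#'
#' Calls cluster when they share the SV type (when `type_strict`), their
#' start breakpoints lie within `max_distance`, and the ratio of the smaller
#' to the larger length is at least `size_ratio`. Clustering is greedy
#' against the cluster seed in coordinate order; the representative takes the
#' median start and median length of its members. Per-(sample, caller)
#' support and genotypes are retained.
#'
#' @param calls data.frame
#'   `seq_id,start,end,sv_type,length,caller,sample,genotype`.
#' @param max_distance breakpoint tolerance in bp.
#' @param type_strict require identical SV type within a cluster.
#' @param size_ratio minimum min/max length ratio within a cluster.
#' @param drop_chroms chromosomes whose calls are dropped before merging
#'   (the Y by default: hemizygous calls from a mixed-sex panel are not
#'   comparable across samples).
#' @return list of class `sv_consensus`: `records` data.frame
#'   (`record_id,seq_id,start,end,sv_type,length,n_samples,n_callers`) and
#'   `support` data.frame (`record_id,sample,caller,genotype`).
#' @export
merge_calls <- function(calls, max_distance = 1000, type_strict = TRUE,
                        size_ratio = 0.7,
                        drop_chroms = c("chrY", "Y")) {
  calls <- calls[!calls$seq_id %in% drop_chroms, , drop = FALSE]
  if (is.null(calls$caller)) calls$caller <- "caller"
  if (is.null(calls$sample)) calls$sample <- "sample"
  if (is.null(calls$genotype)) calls$genotype <- "./."
  calls <- calls[order(calls$seq_id, calls$start), , drop = FALSE]
  n <- nrow(calls)
  cluster <- integer(n)
  next_id <- 0L
  seeds <- list()  # per cluster: list(seq_id, type, start, length)
  for (i in seq_len(n)) {
    assigned <- NA_integer_
    for (cid in rev(seq_len(next_id))) {
      s <- seeds[[cid]]
      if (s$seq_id != calls$seq_id[i]) break  # sorted by seq then start
      if (calls$start[i] - s$start > max_distance) break
      if (type_strict && s$type != calls$sv_type[i]) next
      lr <- min(s$length, calls$length[i]) / max(s$length, calls$length[i])
      if (abs(calls$start[i] - s$start) <= max_distance && lr >= size_ratio) {
        assigned <- cid
        break
      }
    }
    if (is.na(assigned)) {
      next_id <- next_id + 1L
      seeds[[next_id]] <- list(seq_id = calls$seq_id[i],
                               type = calls$sv_type[i],
                               start = calls$start[i],
                               length = calls$length[i])
      assigned <- next_id
    }
    cluster[i] <- assigned
  }
  records <- do.call(rbind, lapply(seq_len(next_id), function(cid) {
    m <- calls[cluster == cid, , drop = FALSE]
    st <- stats::median(m$start)
    len <- stats::median(m$length)
    data.frame(record_id = cid, seq_id = m$seq_id[1], start = st,
               end = if (m$sv_type[1] == "INS") st + 1 else st + len,
               sv_type = m$sv_type[1], length = len,
               n_samples = length(unique(m$sample)),
               n_callers = length(unique(m$caller)),
               stringsAsFactors = FALSE)
  }))
  support <- data.frame(record_id = cluster, sample = calls$sample,
                        caller = calls$caller, genotype = calls$genotype,
                        stringsAsFactors = FALSE)
  structure(list(records = records, support = support),
            class = "sv_consensus")
}

#' Filter consensus records to high confidence
#'
#' Default reading (`per_sample = TRUE`): keep records supported in at least
#' `min_samples` distinct samples, each of those samples contributing at
#' least `min_callers` distinct callers. The alternative reading
#' (`per_sample = FALSE`) requires `min_samples` distinct samples and
#' `min_callers` distinct callers overall.
#'
#' @param consensus an `sv_consensus` object.
#' @param min_samples,min_callers support thresholds.
#' @param per_sample which reading of the support rule to apply.
#' @return the filtered `sv_consensus`.
#' @export
high_confidence_filter <- function(consensus, min_samples = 2L,
                                   min_callers = 2L, per_sample = TRUE) {
  sup <- consensus$support
  keep_ids <- vapply(consensus$records$record_id, function(rid) {
    s <- sup[sup$record_id == rid, , drop = FALSE]
    if (per_sample) {
      per <- tapply(s$caller, s$sample, function(x) length(unique(x)))
      sum(per >= min_callers) >= min_samples
    } else {
      length(unique(s$sample)) >= min_samples &&
        length(unique(s$caller)) >= min_callers
    }
  }, logical(1))
  structure(list(
    records = consensus$records[keep_ids, , drop = FALSE],
    support = sup[sup$record_id %in%
                    consensus$records$record_id[keep_ids], , drop = FALSE]),
    class = "sv_consensus")
}

#' Resolve a sample's genotype across callers by priority
#'
#' Returns the genotype of the highest-priority caller that reported the SV.
#' Callers outside the priority list (DYSGU by default) are used only when no
#' listed caller reported, with `fallback = TRUE`. No genotype at all gives
#' `"./."`.
#'
#' @param genotypes named character vector (names are callers).
#' @param priority caller priority order.
#' @return list `genotype`, `caller`, `fallback`.
#' @export
resolve_genotype <- function(genotypes,
                             priority = c("Sniffles2", "cuteSV", "SVIM")) {
  if (length(genotypes) == 0)
    return(list(genotype = "./.", caller = NA_character_, fallback = FALSE))
  for (p in priority) {
    if (p %in% names(genotypes))
      return(list(genotype = unname(genotypes[[p]]), caller = p,
                  fallback = FALSE))
  }
  other <- names(genotypes)[1]
  list(genotype = unname(genotypes[[other]]), caller = other, fallback = TRUE)
}

#' Resolve genotypes for every record and sample in a consensus
#'
#' @param consensus an `sv_consensus` object.
#' @param priority caller priority order.
#' @return data.frame `record_id,sample,genotype,caller,fallback`.
#' @export
resolve_genotypes <- function(consensus,
                              priority = c("Sniffles2", "cuteSV", "SVIM")) {
  sup <- consensus$support
  keys <- unique(sup[, c("record_id", "sample")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- sup[sup$record_id == keys$record_id[i] &
               sup$sample == keys$sample[i], , drop = FALSE]
    g <- stats::setNames(s$genotype, s$caller)
    g <- g[!duplicated(names(g))]
    r <- resolve_genotype(g, priority)
    data.frame(record_id = keys$record_id[i], sample = keys$sample[i],
               genotype = r$genotype, caller = r$caller,
               fallback = r$fallback, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Classify an SV's genomic region against a gene annotation
#'
#' Single label by precedence: exonic > splicing > five_prime_UTR >
#' three_prime_UTR > upstream_1kb > downstream_1kb > intronic > intergenic.
#' Splicing means overlap of the `splice_slack` bp of intron flanking an
#' internal exon boundary. The upstream flank is measured from the
#' transcription start site and the downstream flank from the transcription
#' end site, strand-aware.
#'
#' @param record one SV interval (list/row with `seq_id,start,end`).
#' @param annotation GFF3-style data.frame with `type` in
#'   `{gene, exon, five_prime_UTR, three_prime_UTR}`, plus `strand`.
#' @param tss_flank flank width in bp.
#' @param splice_slack intronic bp adjacent to an exon boundary that count as
#'   splicing.
#' @return one region label.
#' @export
classify_region <- function(record, annotation, tss_flank = 1000,
                            splice_slack = 2) {
  ann <- annotation[annotation$seq_id == record$seq_id, , drop = FALSE]
  hits <- function(df) nrow(df) > 0 &&
    any(.overlap_bp(df$start, df$end, record$start, record$end) > 0)
  exons <- ann[ann$type == "exon", , drop = FALSE]
  genes <- ann[ann$type == "gene", , drop = FALSE]
  if (hits(exons)) return("exonic")
  if (nrow(exons)) {
    ## intron-side slack at internal exon boundaries
    splice <- rbind(
      data.frame(start = exons$start - splice_slack, end = exons$start),
      data.frame(start = exons$end, end = exons$end + splice_slack))
    splice <- splice[splice$end > splice$start, , drop = FALSE]
    ## only boundaries inside a gene body are splice sites
    if (nrow(genes)) {
      inside <- vapply(seq_len(nrow(splice)), function(i)
        any(genes$start < splice$start[i] & splice$end[i] < genes$end),
        logical(1))
      splice <- splice[inside, , drop = FALSE]
    }
    if (hits(splice)) return("splicing")
  }
  if (hits(ann[ann$type == "five_prime_UTR", , drop = FALSE]))
    return("five_prime_UTR")
  if (hits(ann[ann$type == "three_prime_UTR", , drop = FALSE]))
    return("three_prime_UTR")
  if (nrow(genes)) {
    tss <- ifelse(genes$strand == "-", genes$end, genes$start)
    tes <- ifelse(genes$strand == "-", genes$start, genes$end)
    up <- data.frame(start = ifelse(genes$strand == "-", tss, tss - tss_flank),
                     end = ifelse(genes$strand == "-", tss + tss_flank, tss))
    dn <- data.frame(start = ifelse(genes$strand == "-", tes - tss_flank, tes),
                     end = ifelse(genes$strand == "-", tes, tes + tss_flank))
    if (hits(up)) return("upstream_1kb")
    if (hits(dn)) return("downstream_1kb")
    if (hits(genes)) return("intronic")
  }
  "intergenic"
}

#' Classify every consensus record's genomic region
#' @param consensus an `sv_consensus` object.
#' @param annotation gene annotation data.frame (see [classify_region()]).
#' @param ... passed to [classify_region()].
#' @return the consensus with a `region_class` column added to `records`.
#' @export
classify_regions <- function(consensus, annotation, ...) {
  consensus$records$region_class <- vapply(
    seq_len(nrow(consensus$records)), function(i)
      classify_region(consensus$records[i, ], annotation, ...), character(1))
  consensus
}

#' SV length distribution and modes
#'
#' Gaussian kernel density on log10(length) for each SV type, with modes
#' (local maxima whose height is at least `min_height` of the global
#' maximum) back-transformed to bp.
#'
#' @param records consensus `records` data.frame (or anything with
#'   `sv_type` and `length`).
#' @param types SV types to summarize.
#' @param min_length records below this length are excluded (SV definition).
#' @param min_records minimum records per type; below this the KDE is
#'   skipped with a warning.
#' @param min_height mode height threshold relative to the density maximum.
#' @return named list per type: `density` (a [stats::density] object on
#'   log10 bp) and `modes_bp` (numeric).
#' @export
length_distribution <- function(records, types = c("INS", "DEL"),
                                min_length = 50, min_records = 10L,
                                min_height = 0.05) {
  out <- list()
  for (ty in types) {
    len <- records$length[records$sv_type == ty & records$length >= min_length]
    if (length(len) < min_records) {
      warning("length_distribution: fewer than ", min_records, " ", ty,
              " records; KDE skipped")
      out[[ty]] <- list(density = NULL, modes_bp = numeric(0))
      next
    }
    x <- log10(len)
    if (length(unique(x)) == 1) {
      out[[ty]] <- list(density = NULL, modes_bp = 10^x[1])
      next
    }
    d <- stats::density(x)
    y <- d$y
    is_max <- which(diff(sign(diff(y))) == -2) + 1
    is_max <- is_max[y[is_max] >= min_height * max(y)]
    out[[ty]] <- list(density = d, modes_bp = 10^d$x[is_max])
  }
  out
}
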