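#' Median methylation in sliding windows
#'
#' Tiles each chromosome (per platform) with sliding windows and reports the
#' median methylated fraction over the CpG records in each window. Windows
#' with fewer than `min_cpgs` records are dropped; the number dropped is
#' recorded in the `"dropped"` attribute.
#'
#' @param records methylation data.frame
#'   (`seq_id,start,end,coverage,meth_fraction,platform`).
#' @param window window width in bp.
#' @param step step between window starts in bp.
#' @param min_cpgs minimum CpG records per reported window.
#' @param chrom_lengths optional named lengths; defaults to the maximum
#'   record end per chromosome.
#' @return data.frame
#'   `seq_id,platform,window_start,window_end,n_cpgs,median_meth`.
#' @export
window_methylation <- function(records, window = 100000L, step = 50000L,
                               min_cpgs = 10L, chrom_lengths = NULL) {
  if (window <= 0) stop("window_methylation: window must be positive")
  if (is.null(records$platform)) records$platform <- "unknown"
  out <- list(); dropped <- 0L
  for (id in unique(records$seq_id)) {
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[id]] else
      max(records$end[records$seq_id == id])
    starts <- seq(0, max(0, L - 1), by = step)
    for (pf in unique(records$platform)) {
      r <- records[records$seq_id == id & records$platform == pf, ,
                   drop = FALSE]
      if (nrow(r) == 0) next
      ir <- IRanges::IRanges(start = r$start + 1L, width = 1L)
      wir <- IRanges::IRanges(start = starts + 1L,
                              end = pmin(starts + window, L))
      hits <- IRanges::findOverlaps(wir, ir)
      med <- tapply(r$meth_fraction[S4Vectors::subjectHits(hits)],
                    factor(S4Vectors::queryHits(hits),
                           levels = seq_along(starts)),
                    stats::median)
      n <- tabulate(S4Vectors::queryHits(hits), nbins = length(starts))
      keep <- n >= min_cpgs
      dropped <- dropped + sum(!keep & n > 0)
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        seq_id = id, platform = pf, window_start = starts[keep],
        window_end = pmin(starts[keep] + window, L), n_cpgs = n[keep],
        median_meth = as.numeric(med[keep]), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else data.frame(seq_id = character(), platform = character(),
                         window_start = numeric(), window_end = numeric(),
                         n_cpgs = integer(), median_meth = numeric())
  attr(res, "dropped") <- dropped
  res
}

#' Compare methylation between centromeric and non-centromeric windows
#'
#' Windows are assigned to the centromeric compartment when at least half of
#' the window overlaps the centromere call (`assignment = "majority"`), or by
#' window midpoint. The two compartments are compared by a two-sided
#' Mann-Whitney U test on the window medians. When all window values tie
#' exactly, p is reported as 1 (no evidence of a shift).
#'
#' @param windows output of [window_methylation()] for a single chromosome
#'   and platform.
#' @param call centromere interval (list/row with `start,end`).
#' @param assignment `"majority"` or `"midpoint"`.
#' @return list of class `compartment_comparison`: `u_statistic`,
#'   `p_two_sided`, `median_cen`, `median_noncen`, `n_cen`, `n_noncen`,
#'   `direction` (`cen_lower`/`cen_higher`/`none`), `testable`.
#' @export
compare_compartments <- function(windows, call,
                                 assignment = c("majority", "midpoint")) {
  assignment <- match.arg(assignment)
  w <- windows$window_end - windows$window_start
  ov <- .overlap_bp(windows$window_start, windows$window_end,
                    call$start, call$end)
  in_cen <- if (assignment == "majority") ov >= w / 2 else {
    mid <- (windows$window_start + windows$window_end) / 2
    mid >= call$start & mid < call$end
  }
  cen <- windows$median_meth[in_cen]
  non <- windows$median_meth[!in_cen]
  base <- list(median_cen = stats::median(cen),
               median_noncen = stats::median(non),
               n_cen = length(cen), n_noncen = length(non))
  if (length(cen) < 2 || length(non) < 2) {
    return(structure(c(base, list(u_statistic = NA_real_,
                                  p_two_sided = NA_real_,
                                  direction = "none", testable = FALSE)),
                     class = "compartment_comparison"))
  }
  if (length(unique(c(cen, non))) == 1) {
    u <- length(cen) * length(non) / 2
    p <- 1
  } else {
    exact <- length(cen) <= 20 && length(non) <= 20 &&
      !anyDuplicated(c(cen, non))
    wt <- suppressWarnings(stats::wilcox.test(cen, non, exact = exact,
                                              correct = TRUE))
    u <- unname(wt$statistic); p <- wt$p.value
  }
  direction <- if (is.na(p) || p >= 1) "none"
    else if (base$median_cen < base$median_noncen) "cen_lower"
    else if (base$median_cen > base$median_noncen) "cen_higher" else "none"
  structure(c(base, list(u_statistic = u, p_two_sided = p,
                         direction = direction, testable = TRUE)),
            class = "compartment_comparison")
}

#' Scan window sizes for compartment-comparison significance
#'
#' Repeats [compare_compartments()] per chromosome, platform and window size
#' (step = size/2) and counts the comparisons significant at `alpha`.
#'
#' @param records methylation records.
#' @param calls data.frame of centromere calls (`seq_id,start,end`).
#' @param sizes window sizes to scan.
#' @param alpha significance level.
#' @param min_cpgs minimum CpGs per window.
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame `window_size,platform,n_comparisons,n_significant`.
#' @export
scan_window_sizes <- function(records, calls,
                              sizes = c(1e4, 5e4, 1e5, 5e5, 1e6),
                              alpha = 0.05, min_cpgs = 10L,
                              chrom_lengths = NULL) {
  if (is.null(calls) || nrow(calls) == 0)
    return(data.frame(window_size = numeric(), platform = character(),
                      n_comparisons = integer(), n_significant = integer()))
  out <- list()
  platforms <- unique(records$platform)
  for (size in sizes) {
    wm <- window_methylation(records, window = size, step = max(1, size / 2),
                             min_cpgs = min_cpgs,
                             chrom_lengths = chrom_lengths)
    for (pf in platforms) {
      n_comp <- 0L; n_sig <- 0L
      for (k in seq_len(nrow(calls))) {
        w <- wm[wm$seq_id == calls$seq_id[k] & wm$platform == pf, ,
                drop = FALSE]
        if (nrow(w) == 0) next
        cc <- compare_compartments(w, calls[k, ])
        if (!cc$testable) next
        n_comp <- n_comp + 1L
        if (!is.na(cc$p_two_sided) && cc$p_two_sided < alpha)
          n_sig <- n_sig + 1L
      }
      out[[length(out) + 1]] <- data.frame(
        window_size = size, platform = pf, n_comparisons = n_comp,
        n_significant = n_sig, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' CENP-A peak signal per satellite family
#'
#' Each peak is assigned to the repeat family with which it shares the most
#' overlap (peaks overlapping no repeat are counted unassigned and excluded
#' from the test). Per family, the summed peak score is normalized per kb of
#' annotated family sequence. Families with at least `min_peaks` assigned
#' peaks enter a Kruskal-Wallis test on per-peak scores.
#'
#' @param peaks data.frame `seq_id,start,end,score`.
#' @param repeats annotation data.frame `seq_id,start,end,family`.
#' @param min_peaks minimum assigned peaks for a family to enter the test.
#' @return list: `per_family` data.frame
#'   (`family,n_peaks,total_score,family_kb,score_per_kb`), `kruskal`
#'   (`statistic`, `p_value`, `df` or NULL), `n_unassigned`.
#' @export
cenpa_satellite_signal <- function(peaks, repeats, min_peaks = 5L) {
  if (nrow(peaks) == 0)
    return(list(per_family = data.frame(family = character(),
                                        n_peaks = integer(),
                                        total_score = numeric(),
                                        family_kb = numeric(),
                                        score_per_kb = numeric()),
                kruskal = NULL, n_unassigned = 0L))
  assigned <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    r <- repeats[repeats$seq_id == peaks$seq_id[i], , drop = FALSE]
    if (nrow(r) == 0) next
    ov <- .overlap_bp(r$start, r$end, peaks$start[i], peaks$end[i])
    if (max(ov) > 0) {
      by_fam <- tapply(ov, r$family, sum)
      assigned[i] <- names(which.max(by_fam))
    }
  }
  n_unassigned <- sum(is.na(assigned))
  keep <- !is.na(assigned)
  pk <- peaks[keep, , drop = FALSE]
  fam <- assigned[keep]
  fam_kb <- vapply(unique(fam), function(f) {
    rows <- repeats[repeats$family == f, , drop = FALSE]
    sum(vapply(unique(rows$seq_id), function(sid)
      interval_union_length(rows[rows$seq_id == sid,
                                 c("seq_id", "start", "end")]), numeric(1))) / 1000
  }, numeric(1))
  per_family <- data.frame(
    family = unique(fam),
    n_peaks = as.integer(table(factor(fam, levels = unique(fam)))),
    total_score = as.numeric(tapply(pk$score,
                                    factor(fam, levels = unique(fam)), sum)),
    family_kb = fam_kb, stringsAsFactors = FALSE)
  per_family$score_per_kb <- per_family$total_score / per_family$family_kb
  testable <- per_family$family[per_family$n_peaks >= min_peaks]
  kruskal <- NULL
  if (length(testable) >= 2) {
    sel <- fam %in% testable
    kt <- stats::kruskal.test(pk$score[sel], factor(fam[sel]))
    kruskal <- list(statistic = unname(kt$statistic),
                    p_value = kt$p.value, df = unname(kt$parameter))
  }
  list(per_family = per_family[order(-per_family$score_per_kb), ],
       kruskal = kruskal, n_unassigned = n_unassigned)
}
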