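#' Filter inverted-repeat pairs by arm identity
#'
#' Keeps pairs with `percent_identity >= min_identity` (boundary inclusive).
#' The number of rejected pairs is recorded in the `"rejected"` attribute.
#'
#' @param pairs data.frame from `read_annotations(..., "irf_ngs")` (columns
#'   `seq_id,left_start,left_end,right_start,right_end,percent_identity`).
#' @param min_identity percent identity threshold.
#' @return the filtered data.frame.
#' @export
filter_inverted_pairs <- function(pairs, min_identity = 95.0) {
  keep <- pairs$percent_identity >= min_identity
  out <- pairs[keep, , drop = FALSE]
  attr(out, "rejected") <- sum(!keep)
  out
}

#' Coverage of a region by inverted-repeat arms
#'
#' Fraction of the region covered by the union of all arm intervals, plus the
#' fraction covered by full pair spans (left arm start to right arm end,
#' i.e. arms plus loops), and a per-pair length/identity table.
#'
#' @param pairs inverted-pair data.frame.
#' @param region interval (`seq_id,start,end`).
#' @return list: `arm_fraction`, `span_fraction`, `covered_bp`, `pair_table`.
#' @export
inverted_coverage <- function(pairs, region) {
  width <- region$end - region$start
  pairs <- pairs[pairs$seq_id == region$seq_id, , drop = FALSE]
  if (nrow(pairs) == 0)
    return(list(arm_fraction = 0, span_fraction = 0, covered_bp = 0,
                pair_table = data.frame(pair_length = numeric(),
                                        percent_identity = numeric())))
  clip <- function(s, e) {
    df <- data.frame(seq_id = region$seq_id,
                     start = pmax(s, region$start),
                     end = pmin(e, region$end))
    df[df$end > df$start, , drop = FALSE]
  }
  arms <- rbind(clip(pairs$left_start, pairs$left_end),
                clip(pairs$right_start, pairs$right_end))
  spans <- clip(pairs$left_start, pairs$right_end)
  covered <- interval_union_length(arms)
  list(arm_fraction = covered / width,
       span_fraction = interval_union_length(spans) / width,
       covered_bp = covered,
       pair_table = data.frame(
         pair_length = (pairs$left_end - pairs$left_start +
                          pairs$right_end - pairs$right_start) / 2,
         percent_identity = pairs$percent_identity))
}

#' Flag inverted pairs nested inside the largest arm
#'
#' The largest pair (by mean arm length) is the nesting reference. A smaller
#' pair is nested when both of its arms are covered by containment hits
#' (alignments of the largest arm's sequence) over at least `min_cov` of
#' their length.
#'
#' @param pairs inverted-pair data.frame.
#' @param containment_hits alignment hits of the largest arm against the
#'   chromosome (`seq_id,start,end`).
#' @param min_cov minimum covered fraction of each arm.
#' @return the pairs data.frame with added `nested` logical column; the index
#'   of the largest pair is in attribute `"largest"` (never itself flagged).
#' @export
classify_nesting <- function(pairs, containment_hits, min_cov = 0.8) {
  if (nrow(pairs) == 0) {
    pairs$nested <- logical(0)
    return(pairs)
  }
  arm_len <- (pairs$left_end - pairs$left_start +
                pairs$right_end - pairs$right_start) / 2
  largest <- which.max(arm_len)
  cov_frac <- function(s, e) {
    if (is.null(containment_hits) || nrow(containment_hits) == 0) return(0)
    h <- containment_hits
    clipped <- data.frame(seq_id = "x", start = pmax(h$start, s),
                          end = pmin(h$end, e))
    clipped <- clipped[clipped$end > clipped$start, , drop = FALSE]
    if (nrow(clipped) == 0) return(0)
    interval_union_length(clipped) / (e - s)
  }
  nested <- vapply(seq_len(nrow(pairs)), function(i) {
    if (i == largest) return(FALSE)
    cov_frac(pairs$left_start[i], pairs$left_end[i]) >= min_cov &&
      cov_frac(pairs$right_start[i], pairs$right_end[i]) >= min_cov
  }, logical(1))
  pairs$nested <- nested
  attr(pairs, "largest") <- largest
  pairs
}

## round half up to `digits` decimals (matches one-decimal percent reporting)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Tandem repeat unit copy statistics over a region
#'
#' Counts hit copies of a repeat-unit consensus passing identity and
#' hit-coverage thresholds, and the fraction of the region covered by the
#' union of passing hits.
#'
#' @param hits AlignmentHit data.frame (BLAST-style, subject coordinates on
#'   the chromosome; `query_coverage` as a fraction).
#' @param region interval (`seq_id,start,end`).
#' @param unit_name,unit_length reported unit identity.
#' @param min_identity,min_qcov copy-qualification thresholds.
#' @return list of class `repeat_unit_summary`: `unit_name`, `unit_length`,
#'   `copy_count`, `mean_identity`, `covered_bp`, `coverage_fraction`,
#'   `coverage_percent` (rounded half-up to one decimal).
#' @export
tandem_unit_stats <- function(hits, region, unit_name = "unit",
                              unit_length = NA, min_identity = 90,
                              min_qcov = 0.8) {
  h <- hits[hits$seq_id == region$seq_id, , drop = FALSE]
  qc <- if (!is.null(h$query_coverage)) h$query_coverage else 1
  pass <- h$percent_identity >= min_identity & (is.na(qc) | qc >= min_qcov)
  h <- h[pass, , drop = FALSE]
  width <- region$end - region$start
  if (nrow(h) == 0) {
    return(structure(list(unit_name = unit_name, unit_length = unit_length,
                          copy_count = 0L, mean_identity = NA_real_,
                          covered_bp = 0, coverage_fraction = 0,
                          coverage_percent = 0),
                     class = "repeat_unit_summary"))
  }
  clipped <- data.frame(seq_id = region$seq_id,
                        start = pmax(h$start, region$start),
                        end = pmin(h$end, region$end))
  clipped <- clipped[clipped$end > clipped$start, , drop = FALSE]
  covered <- interval_union_length(clipped)
  structure(list(unit_name = unit_name, unit_length = unit_length,
                 copy_count = nrow(h),
                 mean_identity = mean(h$percent_identity),
                 covered_bp = covered,
                 coverage_fraction = covered / width,
                 coverage_percent = round_half_up(100 * covered / width, 1)),
            class = "repeat_unit_summary")
}

#' Detect complete rDNA units from 18S/5.8S/28S subunit hits
#'
#' Hits failing the identity, query-coverage or e-value thresholds are
#' dropped. Surviving hits are chained along each sequence; a chain is a
#' complete unit when it contains 18S -> 5.8S -> 28S in coordinate order on
#' the + orientation (or 28S -> 5.8S -> 18S on -, all hits minus-strand),
#' with consecutive subunits at most `max_intra_unit_gap` apart.
#'
#' @param hits AlignmentHit data.frame with `query_id` in
#'   `{"18S","5.8S","28S"}` and subject `seq_id,start,end,strand`.
#' @param max_intra_unit_gap maximum bp between consecutive subunits.
#' @param min_identity,min_qcov,max_evalue hit filters.
#' @return data.frame of complete units:
#'   `seq_id,start,end,orientation,complete`.
#' @export
detect_rdna_units <- function(hits, max_intra_unit_gap = 50000,
                              min_identity = 85.0, min_qcov = 0.80,
                              max_evalue = 1e-10) {
  empty <- data.frame(seq_id = character(), start = numeric(),
                      end = numeric(), orientation = character(),
                      complete = logical())
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  qc <- if (!is.null(hits$query_coverage)) hits$query_coverage else NA
  pass <- hits$percent_identity >= min_identity &
    hits$evalue <= max_evalue & (is.na(qc) | qc >= min_qcov)
  h <- hits[pass, , drop = FALSE]
  if (nrow(h) == 0) return(empty)
  out <- list()
  for (id in unique(h$seq_id)) {
    hh <- h[h$seq_id == id, , drop = FALSE]
    hh <- hh[order(hh$start), , drop = FALSE]
    used <- rep(FALSE, nrow(hh))
    find_next <- function(after_end, subunit, strand) {
      cand <- which(!used & hh$query_id == subunit & hh$strand == strand &
                      hh$start >= after_end &
                      hh$start - after_end <= max_intra_unit_gap)
      if (length(cand)) cand[1] else NA_integer_
    }
    for (i in seq_len(nrow(hh))) {
      if (used[i]) next
      strand <- hh$strand[i]
      order_needed <- if (strand == "+") c("18S", "5.8S", "28S")
                      else c("28S", "5.8S", "18S")
      if (hh$query_id[i] != order_needed[1]) next
      j <- find_next(hh$end[i], order_needed[2], strand)
      if (is.na(j)) next
      k <- find_next(hh$end[j], order_needed[3], strand)
      if (is.na(k)) next
      used[c(i, j, k)] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        seq_id = id, start = hh$start[i], end = hh$end[k],
        orientation = strand, complete = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
  else empty
}
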