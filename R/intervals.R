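#' Construct a table of genomic intervals
#'
#' All coordinates inside the package are 0-based, half-open \code{[start, end)}.
#' Conversion from 1-based inclusive conventions (GFF3, RepeatMasker, BLAST)
#' happens only at parse/serialize boundaries.
#'
#' @param seq_id character vector of sequence identifiers.
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, 0-based exclusive end; must satisfy `start < end`.
#' @param strand character vector in `{"+", "-", "."}`.
#' @return A data.frame with columns `seq_id`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = ".") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be numeric and non-missing")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  data.frame(seq_id = as.character(seq_id), start = start, end = end,
             strand = rep_len(as.character(strand), length(start)),
             stringsAsFactors = FALSE)
}

## IRanges is 1-based closed; shift by +1 on the way in only.
.as_iranges <- function(intervals) {
  IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
}

.from_iranges <- function(ir, seq_id = NA_character_) {
  data.frame(seq_id = seq_id, start = IRanges::start(ir) - 1,
             end = IRanges::end(ir), strand = ".", stringsAsFactors = FALSE)
}

#' Total length of the union of a set of intervals
#'
#' Overlapping bases are counted once. All intervals must lie on a single
#' sequence.
#'
#' @param intervals interval data.frame (see [genomic_interval()]); may be
#'   empty.
#' @return Integer number of base pairs covered.
#' @export
interval_union_length <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(0L)
  if (length(unique(intervals$seq_id)) > 1)
    stop("interval_union_length: intervals span multiple seq_ids: ",
         paste(unique(intervals$seq_id), collapse = ", "))
  sum(IRanges::width(IRanges::reduce(.as_iranges(intervals))))
}

#' Merge overlapping intervals on one sequence
#' @param intervals interval data.frame on a single seq_id.
#' @return data.frame of disjoint, sorted intervals covering the same bases.
#' @export
merge_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0)
    return(genomic_interval(character(), numeric(), numeric())[0, ])
  if (length(unique(intervals$seq_id)) > 1)
    stop("merge_intervals: intervals span multiple seq_ids")
  .from_iranges(IRanges::reduce(.as_iranges(intervals)),
                seq_id = intervals$seq_id[1])
}

## bp of overlap between each row of `a` and the single interval
## (qstart, qend); vectorized over `a`.
.overlap_bp <- function(a_start, a_end, qstart, qend) {
  pmax(0, pmin(a_end, qend) - pmax(a_start, qstart))
}

## Union bp of `intervals` falling inside [qstart, qend) on one seq_id.
.union_overlap_bp <- function(intervals, qstart, qend) {
  if (nrow(intervals) == 0) return(0)
  m <- merge_intervals(intervals)
  sum(.overlap_bp(m$start, m$end, qstart, qend))
}
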