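.SAT_FAMILIES <- c("SATI", "SATII", "SATIII", "SATIV", "SATV", "SATVI",
                   "SATVII")

## subset an annotation table to the satellite families, exact family match
.satellite_rows <- function(annotations, satellite_families) {
  annotations[annotations$family %in% satellite_families, , drop = FALSE]
}

#' Qualify consecutive windows by satellite content
#'
#' Tiles a chromosome with consecutive windows (non-overlapping by default)
#' and computes, per window, the interval-union satellite bp. A window
#' qualifies when its satellite bp reaches `min_sat`.
#'
#' @param annotations repeat annotation data.frame for one chromosome
#'   (columns `seq_id,start,end,family`).
#' @param chrom_length chromosome length in bp.
#' @param window window width in bp (default 100 kb).
#' @param step tiling step (default = window: consecutive windows).
#' @param min_sat satellite bp threshold per window (default 20 kb).
#' @param satellite_families families counted as satellite.
#' @return data.frame `window_start,window_end,satellite_bp,qualifies`.
#' @export
qualify_windows <- function(annotations, chrom_length, window = 100000L,
                            step = window, min_sat = 20000L,
                            satellite_families = .SAT_FAMILIES) {
  if (window <= 0) stop("qualify_windows: window must be positive")
  if (nrow(annotations) && length(unique(annotations$seq_id)) > 1)
    stop("qualify_windows: annotations must be on a single chromosome")
  starts <- seq(0, max(0, chrom_length - 1), by = step)
  ends <- pmin(starts + window, chrom_length)
  sat <- .satellite_rows(annotations, satellite_families)
  merged <- if (nrow(sat)) merge_intervals(sat[, c("seq_id", "start", "end")])
            else NULL
  bp <- vapply(seq_along(starts), function(k) {
    if (is.null(merged)) return(0)
    sum(.overlap_bp(merged$start, merged$end, starts[k], ends[k]))
  }, numeric(1))
  data.frame(window_start = starts, window_end = ends, satellite_bp = bp,
             qualifies = bp >= min_sat)
}

#' Call a centromere from qualifying satellite windows
#'
#' The centromere cluster is the maximal run of consecutive qualifying
#' windows nearest the p terminus, sought downstream of the telomeric region
#' (chromosomes without a telomere tract use the chromosome start). The call
#' boundaries are snapped to the first and last satellite-annotated base
#' within the cluster span.
#'
#' @param qualifications output of [qualify_windows()].
#' @param annotations repeat annotation data.frame for the chromosome.
#' @param telomere_tract optional tract from [detect_telomere_tract()] at the
#'   p terminus; its end bounds the search start.
#' @param satellite_families families counted as satellite.
#' @return list (`seq_id,start,end,windows,family_composition`) or NULL when
#'   no window qualifies.
#' @export
call_centromere <- function(qualifications, annotations,
                            telomere_tract = NULL,
                            satellite_families = .SAT_FAMILIES) {
  q <- qualifications
  tel_end <- if (is.null(telomere_tract)) 0 else telomere_tract$end
  eligible <- q$qualifies & q$window_end > tel_end
  if (!any(eligible)) return(NULL)
  r <- rle(eligible)
  run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths + 1
  runs <- which(r$values)
  best <- runs[1]                     # p-proximal cluster
  span0 <- q$window_start[run_start[best]]
  span1 <- q$window_end[run_end[best]]
  sat <- .satellite_rows(annotations, satellite_families)
  sat <- sat[sat$end > max(span0, tel_end) & sat$start < span1, , drop = FALSE]
  if (nrow(sat) == 0) return(NULL)
  start <- max(min(sat$start), tel_end)
  end <- max(sat$end)
  comp <- tapply(seq_len(nrow(sat)), sat$family, function(i)
    interval_union_length(sat[i, c("seq_id", "start", "end")]))
  list(seq_id = annotations$seq_id[1], start = start, end = end,
       windows = q[run_start[best]:run_end[best], , drop = FALSE],
       family_composition = as.list(comp))
}

#' Report the dominant-family order across the p arm and centromere
#'
#' Bins the region from the chromosome start to the centromere end and
#' reports the dominant annotation family per bin (the telomere tract is
#' labelled `telomere`), collapsed to a run order. Checks whether the
#' canonical prefix telomere -> SATVII -> SATII -> SATIV holds as an ordered
#' subsequence.
#'
#' @param call centromere call from [call_centromere()].
#' @param annotations repeat annotation data.frame.
#' @param telomere_tract optional p-terminus tract.
#' @param bin bin width in bp.
#' @return list with `order` (character vector of dominant families) and
#'   `canonical` (logical).
#' @export
check_canonical_order <- function(call, annotations, telomere_tract = NULL,
                                  bin = 10000L) {
  if (is.null(call)) stop("check_canonical_order: no centromere call")
  stops <- seq(0, call$end, by = bin)
  ann <- annotations
  if (!is.null(telomere_tract)) {
    ann <- rbind(ann[, c("seq_id", "start", "end", "family")],
                 data.frame(seq_id = call$seq_id,
                            start = telomere_tract$start,
                            end = telomere_tract$end, family = "telomere"))
  } else {
    ann <- ann[, c("seq_id", "start", "end", "family")]
  }
  dominant <- vapply(stops, function(s) {
    e <- s + bin
    ov <- .overlap_bp(ann$start, ann$end, s, e)
    if (all(ov == 0)) return(NA_character_)
    by_fam <- tapply(ov, ann$family, sum)
    names(which.max(by_fam))
  }, character(1))
  order_seq <- rle(dominant[!is.na(dominant)])$values
  canon <- c("telomere", "SATVII", "SATII", "SATIV")
  pos <- match(canon, order_seq)
  canonical <- !anyNA(pos) && all(diff(pos) > 0)
  list(order = order_seq, canonical = canonical)
}

#' Classify centromere structure from satellite interspersion
#'
#' A call whose satellite fraction is below `neo_cutoff` is
#' `neocentromere_like`. Otherwise the SATI/SATVI interspersion decides:
#' counting transitions between maximal SATI runs and SATVI runs along the
#' call, at least `min_transitions_s1` transitions gives `structure1`, at
#' most `max_transitions_s2` gives `structure2`, anything between is
#' `undetermined`.
#'
#' @param call centromere call (list with `seq_id,start,end`).
#' @param annotations repeat annotation data.frame.
#' @param neo_cutoff satellite-fraction cutoff below which the call is
#'   neocentromere-like.
#' @param min_transitions_s1,max_transitions_s2 transition-count cutoffs.
#' @param satellite_families families counted as satellite.
#' @return one of `"structure1"`, `"structure2"`, `"neocentromere_like"`,
#'   `"undetermined"`.
#' @export
classify_structure <- function(call, annotations, neo_cutoff = 0.05,
                               min_transitions_s1 = 4L,
                               max_transitions_s2 = 1L,
                               satellite_families = .SAT_FAMILIES) {
  if (is.null(call)) stop("classify_structure: no centromere call")
  width <- call$end - call$start
  sat <- .satellite_rows(annotations, satellite_families)
  sat <- sat[sat$end > call$start & sat$start < call$end, , drop = FALSE]
  sat_bp <- if (nrow(sat)) {
    clipped <- sat
    clipped$start <- pmax(clipped$start, call$start)
    clipped$end <- pmin(clipped$end, call$end)
    interval_union_length(clipped[, c("seq_id", "start", "end")])
  } else 0
  if (sat_bp / width < neo_cutoff) return("neocentromere_like")
  iv <- sat[sat$family %in% c("SATI", "SATVI"), , drop = FALSE]
  if (nrow(iv) == 0) return("undetermined")
  iv <- iv[order(iv$start), , drop = FALSE]
  runs <- rle(iv$family)$values
  transitions <- length(runs) - 1L
  if (transitions >= min_transitions_s1) "structure1"
  else if (transitions <= max_transitions_s2) "structure2"
  else "undetermined"
}

#' Map centromeres across a whole genome
#'
#' Convenience wrapper running window qualification, centromere calling,
#' structure classification and the canonical-order check per chromosome.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param annotations repeat annotations for all chromosomes.
#' @param window,min_sat see [qualify_windows()].
#' @param telomere_unit unit used to locate the p-arm telomere.
#' @param satellite_families families counted as satellite.
#' @return data.frame with one row per called centromere:
#'   `seq_id,start,end,structure,canonical_order`.
#' @export
map_centromeres <- function(genome, annotations, window = 100000L,
                            min_sat = 20000L, telomere_unit = "TTAGGG",
                            satellite_families = .SAT_FAMILIES) {
  out <- list()
  for (id in names(genome)) {
    ann <- annotations[annotations$seq_id == id, , drop = FALSE]
    if (nrow(ann) == 0) next
    tel <- detect_telomere_tract(genome[[id]], "p", unit = telomere_unit)
    q <- qualify_windows(ann, length(genome[[id]]), window = window,
                         min_sat = min_sat,
                         satellite_families = satellite_families)
    call <- call_centromere(q, ann, tel,
                            satellite_families = satellite_families)
    if (is.null(call)) next
    structure <- classify_structure(call, ann,
                                    satellite_families = satellite_families)
    ord <- check_canonical_order(call, ann, tel)
    out[[length(out) + 1]] <- data.frame(
      seq_id = id, start = call$start, end = call$end,
      structure = structure, canonical_order = ord$canonical,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(), start = numeric(), end = numeric(),
               structure = character(), canonical_order = logical())
}
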