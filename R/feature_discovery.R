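#' Identify newly annotated features by annotation complement
#'
#' A target feature is "shared" when some lifted reference feature overlaps
#' at least `min_overlap_fraction` of the target feature's length (in
#' reciprocal mode the overlap must also cover that fraction of the lifted
#' feature). New features are the complement: target features that are not
#' shared. Overlap is computed on feature spans, strand-blind.
#'
#' @param lifted_reference data.frame of reference features lifted onto the
#'   target coordinates (`seq_id,start,end,feature_id,biotype`).
#' @param target data.frame of target-assembly features (same columns).
#' @param min_overlap_fraction required overlap as a fraction of the target
#'   feature length.
#' @param reciprocal require the fraction of both features.
#' @param same_biotype only count overlaps between features of the same
#'   biotype.
#' @return list: `new_features` (data.frame), `counts` (named integer per
#'   biotype, summing to `nrow(new_features)`).
#' @export
find_new_features <- function(lifted_reference, target,
                              min_overlap_fraction = 0.90,
                              reciprocal = FALSE, same_biotype = FALSE) {
  if (nrow(target) > 0 && nrow(lifted_reference) > 0) {
    shared_ids <- intersect(unique(target$seq_id),
                            unique(lifted_reference$seq_id))
    if (length(shared_ids) == 0)
      stop("find_new_features: no shared sequence identifiers; target has [",
           paste(unique(target$seq_id), collapse = ","),
           "], lifted has [",
           paste(unique(lifted_reference$seq_id), collapse = ","), "]")
  }
  is_shared <- vapply(seq_len(nrow(target)), function(i) {
    t_len <- target$end[i] - target$start[i]
    lr <- lifted_reference[lifted_reference$seq_id == target$seq_id[i], ,
                           drop = FALSE]
    if (same_biotype)
      lr <- lr[lr$biotype == target$biotype[i], , drop = FALSE]
    if (nrow(lr) == 0) return(FALSE)
    ov <- .overlap_bp(lr$start, lr$end, target$start[i], target$end[i])
    ok <- ov >= min_overlap_fraction * t_len
    if (reciprocal)
      ok <- ok & ov >= min_overlap_fraction * (lr$end - lr$start)
    any(ok)
  }, logical(1))
  new_features <- target[!is_shared, , drop = FALSE]
  counts <- table(new_features$biotype)
  list(new_features = new_features,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Features contained in a region
#'
#' Returns features whose overlap with the region is at least
#' `min_containment` of the feature's own length.
#'
#' @param features data.frame (`seq_id,start,end`, optionally `biotype`).
#' @param region interval (`seq_id,start,end`).
#' @param min_containment required contained fraction of the feature length
#'   (1.0 = fully contained).
#' @param biotype optional biotype filter.
#' @return the qualifying subset of `features`.
#' @export
genes_in_region <- function(features, region, min_containment = 0.5,
                            biotype = NULL) {
  f <- features[features$seq_id == region$seq_id, , drop = FALSE]
  if (!is.null(biotype)) f <- f[f$biotype %in% biotype, , drop = FALSE]
  if (nrow(f) == 0) return(f)
  ov <- .overlap_bp(f$start, f$end, region$start, region$end)
  f[ov >= min_containment * (f$end - f$start), , drop = FALSE]
}
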