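#' Dinucleotide profile of a genomic region
#'
#' Counts every overlapping forward-strand dinucleotide whose two bases are
#' both in `{A,C,G,T}` (windows containing N are skipped), plus the A/C/G/T
#' base counts over the region's non-N positions. The number of valid
#' dinucleotide windows equals the sum of the 16 counts.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param region interval (list or one-row data.frame with
#'   `seq_id,start,end`; 0-based half-open).
#' @param both_strands when TRUE, counts are aggregated with their reverse
#'   complements (CpG is strand-symmetric; TpG is not, hence the
#'   single-strand default).
#' @return list of class `dinucleotide_profile`: `region`, `counts` (named
#'   16-vector), `base_counts` (named 4-vector), `n_windows`.
#' @export
profile_region <- function(genome, region, both_strands = FALSE) {
  id <- as.character(region$seq_id)
  if (!id %in% names(genome)) stop("unknown sequence: ", id)
  L <- length(genome[[id]])
  if (region$start < 0 || region$end > L || region$start >= region$end)
    stop(sprintf("region [%d,%d) outside sequence %s (length %d)",
                 region$start, region$end, id, L))
  sub <- Biostrings::subseq(genome[[id]], region$start + 1, region$end)
  counts <- Biostrings::dinucleotideFrequency(sub, step = 1)
  if (both_strands) {
    rc <- Biostrings::dinucleotideFrequency(
      Biostrings::reverseComplement(sub), step = 1)
    counts <- counts + rc
  }
  af <- Biostrings::alphabetFrequency(sub)
  base_counts <- af[c("A", "C", "G", "T")]
  if (both_strands) {
    comp <- base_counts[c("T", "G", "C", "A")]
    names(comp) <- c("A", "C", "G", "T")
    base_counts <- base_counts + comp
  }
  structure(list(region = data.frame(seq_id = id, start = region$start,
                                     end = region$end),
                 counts = counts, base_counts = base_counts,
                 n_windows = sum(counts)),
            class = "dinucleotide_profile")
}

#' Sum two dinucleotide profiles
#' @param a,b `dinucleotide_profile` objects on the same sequence.
#' @return a combined profile (region spans both inputs).
#' @export
combine_profiles <- function(a, b) {
  structure(list(region = data.frame(seq_id = a$region$seq_id,
                                     start = min(a$region$start, b$region$start),
                                     end = max(a$region$end, b$region$end)),
                 counts = a$counts + b$counts,
                 base_counts = a$base_counts + b$base_counts,
                 n_windows = a$n_windows + b$n_windows),
            class = "dinucleotide_profile")
}

#' CpG summary statistics from a dinucleotide profile
#'
#' Expected CpG under base-composition independence is
#' `nC * nG / n_windows`, keeping observed and expected on the same support
#' (valid dinucleotide windows). The observed/expected TpG ratio uses
#' `nT * nG / n_windows` analogously.
#'
#' @param profile a [profile_region()] result.
#' @return list of class `cpg_stats`: `observed_cpg`, `expected_cpg`,
#'   `oe_ratio`, `cpg_noncpg_ratio`, `tpg_count`, `obs_exp_tpg`,
#'   `n_windows`. Ratios with a zero denominator are `NA` (undefined), never
#'   0.
#' @export
cpg_stats <- function(profile) {
  if (profile$n_windows <= 0) stop("cpg_stats: empty profile")
  ## numeric, not integer: nC * nG overflows 32-bit at megabase scale
  obs <- as.numeric(profile$counts["CG"])
  nC <- as.numeric(profile$base_counts["C"])
  nG <- as.numeric(profile$base_counts["G"])
  nT <- as.numeric(profile$base_counts["T"])
  nw <- as.numeric(profile$n_windows)
  exp_cpg <- nC * nG / nw
  exp_tpg <- nT * nG / nw
  tpg <- unname(profile$counts["TG"])
  structure(list(
    observed_cpg = obs,
    expected_cpg = exp_cpg,
    oe_ratio = if (exp_cpg > 0) obs / exp_cpg else NA_real_,
    cpg_noncpg_ratio = if (nw > obs) obs / (nw - obs) else NA_real_,
    tpg_count = tpg,
    obs_exp_tpg = if (exp_tpg > 0) tpg / exp_tpg else NA_real_,
    n_windows = nw), class = "cpg_stats")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value (hypergeometric tail summation, as in
#' [stats::fisher.test()]) with the sample cross-product odds ratio
#' `(a*d)/(b*c)`. Zero-cell tables give an infinite or zero odds ratio,
#' flagged in `degenerate`.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise).
#' @return list `odds_ratio`, `p_two_sided`, `degenerate`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("fisher_2x2: cells must be non-negative")
  if (sum(cells) == 0) stop("fisher_2x2: table is all zero")
  p <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf else NaN
  list(odds_ratio = or, p_two_sided = p,
       degenerate = b * c == 0 || a * d == 0)
}

#' CpG enrichment tests between a centromeric and a non-centromeric profile
#'
#' Two 2x2 Fisher exact tests: (i) CpG vs non-CpG windows crossed with
#' centromere vs non-centromere; (ii) CpG vs TpG windows crossed with
#' centromere vs non-centromere. Direction flags report which compartment is
#' CpG-enriched (test i) and whether the centromere shows TpG excess
#' relative to CpG (test ii).
#'
#' @param profile_cen,profile_noncen [profile_region()] results.
#' @return data.frame with one row per test: `test`, `odds_ratio`,
#'   `p_two_sided`, `direction`.
#' @export
centromere_enrichment_tests <- function(profile_cen, profile_noncen) {
  if (profile_cen$n_windows == 0 || profile_noncen$n_windows == 0)
    stop("centromere_enrichment_tests: empty profile")
  cg_c <- unname(profile_cen$counts["CG"])
  cg_n <- unname(profile_noncen$counts["CG"])
  tg_c <- unname(profile_cen$counts["TG"])
  tg_n <- unname(profile_noncen$counts["TG"])
  t1 <- fisher_2x2(cg_c, profile_cen$n_windows - cg_c,
                   cg_n, profile_noncen$n_windows - cg_n)
  t2 <- fisher_2x2(cg_c, tg_c, cg_n, tg_n)
  dir1 <- if (t1$odds_ratio > 1) "cen_enriched" else
          if (t1$odds_ratio < 1) "cen_depleted" else "none"
  dir2 <- if (t2$odds_ratio < 1) "cen_tpg_excess" else
          if (t2$odds_ratio > 1) "cen_cpg_excess" else "none"
  data.frame(test = c("cpg_vs_noncpg", "cpg_vs_tpg"),
             odds_ratio = c(t1$odds_ratio, t2$odds_ratio),
             p_two_sided = c(t1$p_two_sided, t2$p_two_sided),
             direction = c(dir1, dir2), stringsAsFactors = FALSE)
}

#' Observed-vs-expected CpG regression across regions
#'
#' Ordinary least squares of observed CpG count on expected CpG count across
#' regions (one point per centromere), with Pearson correlation and
#' externally studentized residual outlier flags.
#'
#' @param stats_list named list of [cpg_stats()] results (names are region
#'   labels).
#' @param outlier_threshold absolute externally studentized residual above
#'   which a region is flagged.
#' @return list: `pearson_r`, `p_value`, `slope`, `intercept`, `residuals`
#'   (studentized, named), `outliers` (character labels), `fit` (the `lm`
#'   object).
#' @export
regress_obs_exp <- function(stats_list, outlier_threshold = 3) {
  if (length(stats_list) < 3)
    stop("regress_obs_exp: need at least 3 regions")
  obs <- vapply(stats_list, function(s) s$observed_cpg, numeric(1))
  exp_ <- vapply(stats_list, function(s) s$expected_cpg, numeric(1))
  fit <- stats::lm(obs ~ exp_)
  ct <- stats::cor.test(exp_, obs)
  rs <- stats::rstudent(fit)
  names(rs) <- names(stats_list)
  outliers <- names(rs)[is.finite(rs) & abs(rs) > outlier_threshold]
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = rs, outliers = outliers, fit = fit)
}
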