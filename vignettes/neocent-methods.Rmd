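---
title: "Methods and design of the neocent toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the neocent toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`neocent` characterizes complete (telomere-to-telomere) mammalian assemblies
with an emphasis on centromere biology: canonical satellite-array centromeres
on acrocentric autosomes versus a satellite-free neocentromere on a
submetacentric X chromosome, as found in cattle. The package consumes the
outputs of standard upstream tools (RepeatMasker, Inverted Repeats Finder,
BLASTN, methylation callers, peak callers, SV callers) and implements the
downstream statistics; it does not re-implement any of those upstream
searches.

All internal coordinates are 0-based, half-open. Conversion from 1-based
inclusive conventions (GFF3, RepeatMasker `.out`, BLAST subject coordinates)
happens only in `read_annotations()`; BLAST hits with subject start > end are
flagged minus-strand and swapped. Sequences are restricted to
`{A,C,G,T,N}`; other IUPAC codes are mapped to N on read and counted, because
every downstream statistic defines its behavior over that alphabet only.

# Centromere boundary detection

Satellite-cluster centromeres are detected from repeat annotations alone
(`qualify_windows()`, `call_centromere()`). Consecutive windows (default
100 kb, non-overlapping, since the procedure is defined on consecutive
windows rather than sliding ones) qualify when their interval-union satellite
content reaches a threshold (default 20 kb). The centromere is the maximal
run of consecutive qualifying windows nearest the p terminus — all cattle
autosomes are acrocentric — with boundaries snapped to the first satellite
base downstream of the p-arm telomere tract and the last satellite base in
the cluster. When a chromosome has no detectable telomere tract the
chromosome start stands in for the telomere, since centromeres are still
expected on telomere-less assemblies.

Structure classification (`classify_structure()`) separates three cases:

* `neocentromere_like` — satellite fraction of the call below 5%. The small
  tolerance avoids reclassifying on trace satellite hits (a real X
  neocentromere can carry a few stray satellite copies).
* `structure1` vs `structure2` — decided by SATI/SATVI interspersion. We
  count transitions between maximal SATI runs and SATVI runs across the
  call: >= 4 transitions gives structure 1 (interspersed), <= 1 gives
  structure 2 (essentially a single SATI -> SATVI changeover), anything
  between is `undetermined`. There is no published numeric rule for this
  distinction; the transition count is this package's operationalization and
  both cutoffs are arguments.

`check_canonical_order()` reports the dominant annotation family per bin from
the p terminus through the centromere and verifies the canonical prefix
telomere -> SATVII -> SATII -> SATIV as an ordered subsequence. This is a
prefix check on dominant families, deliberately tolerant of the SINE/LINE and
simple-repeat interruptions that occur inside the SATVII zone.

# Dinucleotide statistics and the deamination signature

`profile_region()` counts all overlapping forward-strand dinucleotides whose
two bases are both in `{A,C,G,T}`; windows containing N are skipped, and the
number of valid windows is the sum of the 16 counts. Forward-strand counting
is the default because TpG — unlike CpG — is not strand-symmetric, and the
signature of interest is specifically TpG excess (CpG -> TpG deamination on
the forward strand, CpG -> CpA on the reverse). A `both_strands` flag
aggregates reverse-complement counts when symmetry is wanted.

Expected CpG under base-composition independence is `nC * nG / n_windows`,
with the number of valid windows — not the raw length — as the denominator so
observed and expected share the same support across N-gaps. Key ratios:

* CpG O/E = observed / expected; 1.0 for an i.i.d. sequence, and depressed
  by historical methylation-deamination.
* CpG : non-CpG = observed / (windows − observed), the compact depletion
  summary used for cross-compartment comparison.
* TpG O/E, computed analogously with `nT`.

Enrichment is tested with Fisher's exact test on two 2×2 tables (CpG vs
non-CpG × compartment; CpG vs TpG × compartment). The p-value comes from
`stats::fisher.test` (hypergeometric tail summation); the odds ratio is
reported as the sample cross-product ratio `(a d)/(b c)` rather than the
conditional MLE, because the cross-product is what the 2×2 construction
defines; zero cells flag the ratio as degenerate instead of silently
reporting 0.

The cross-centromere regression (`regress_obs_exp()`) fits observed on
expected CpG counts by OLS and flags outliers at |externally studentized
residual| > 3. The threshold is a package decision (configurable): it flags
a point whose deletion-fit prediction is grossly violated, which is the
behavior wanted for a single aberrant (neo)centromere among ordinary ones.

`deaminate()` provides the generative counterpart: each CpG converts
independently with probability d, split evenly between TpG (C→T) and CpA
(G→A) products for biochemical symmetry; a single-strand mode produces TpG
only. The package's invariant — mean CpG O/E strictly decreasing in d across
{0, 0.25, 0.5, 0.75, 1} — is exercised over 20 seeds per rate.

# Methylation compartment comparison

`window_methylation()` computes the median methylated fraction per sliding
window (default 100 kb windows, 50 kb step), dropping windows with fewer
than 10 CpGs. `compare_compartments()` assigns a window to the centromeric
compartment when at least half of it overlaps the call (a `midpoint` mode is
available; for windows much smaller than the centromere the two agree), and
applies a two-sided Mann-Whitney U test to the window medians. Ties are
handled by mid-ranks with the normal approximation above group size 20 and
the exact distribution below; when every window value is identical the
p-value is reported as 1 directly, since the rank test carries no evidence in
that degenerate case. No cross-chromosome multiple-testing correction is
applied by default because per-chromosome significance counts are the quantity
of interest; callers can correct externally.

A caveat the test suite respects: with a 2:1 step-to-window overlap adjacent
window medians are positively correlated, which makes the U test mildly
anti-conservative. The power checks use the overlapping default; the null
calibration checks use non-overlapping windows and ~100 windows per
chromosome so the p-value distribution is on the near-continuous rank-sum
path.

`cenpa_satellite_signal()` assigns each peak to the repeat family with
maximal overlap (peaks with no overlap are excluded and counted), normalizes
summed peak score per kb of annotated family sequence, and compares per-peak
scores across families by Kruskal-Wallis. "Per kb of family sequence" is this
package's reading of a normalized family signal; a per-copy mean is a
straightforward alternative on the returned table.

# Inverted repeats, tandem units and rDNA

Inverted-repeat pairs are filtered at >= 95% arm identity (boundary
inclusive). Coverage of a region is reported two ways — union of arms only,
and union of full pair spans (arms plus loops) — because published coverage
figures do not always state which is meant. Nesting requires both arms of a
smaller pair covered >= 80% of their length by alignments of the largest arm;
the both-arm rule prevents calling a pair nested on a single-arm hit.

`tandem_unit_stats()` counts unit copies passing >= 90% identity and >= 80%
hit coverage of the unit consensus, and reports the union coverage fraction
of the region, rounded half-up to one decimal in percent form to match the
one-decimal reporting style of genome papers.

`detect_rdna_units()` drops subunit hits failing 85% identity / 80% query
coverage / 1e-10 e-value and chains survivors along each sequence: a complete
unit is 18S -> 5.8S -> 28S in coordinate order (reversed on the minus
strand, all hits on one strand), with consecutive subunits at most 50 kb
apart. The gap bound is a package decision: a full rDNA unit spans roughly
35 kb, so 50 kb bounds one unit while still separating tandem neighbours; it
is an argument for unusual spacer architectures. Chaining is greedy
left-to-right with each hit consumed at most once, so tandem arrays resolve
into exactly one unit per planted repeat.

# New-feature discovery

A target feature is shared when a lifted reference feature of any biotype
overlaps at least 90% of the target feature's length; new features are the
complement. The 90% rule is read against the target (candidate) feature's
length; a reciprocal mode additionally requires 90% of the lifted feature,
and a same-biotype mode restricts the comparison, since the published
procedure is ambiguous on both points. Overlap is computed on feature spans,
strand-blind — exon-level matching is deliberately out of scope.

# SV consensus

`merge_calls()` clusters calls of the same type with breakpoints within
1 kb and a min/max length ratio of at least 0.7 — the conventional defaults
of multi-caller SV mergers — taking the median start and length as the
representative and retaining per-(sample, caller) support. The
high-confidence rule "at least two samples by at least two callers" is read
as: at least two samples each supported by at least two distinct callers; the
weaker reading (two samples total and two callers total) is available via
`per_sample = FALSE`. Genotypes resolve by the priority Sniffles2 > cuteSV >
SVIM; DYSGU is outside the priority list and is used only as a flagged
fallback when no listed caller reported. Y-chromosome calls are dropped by
default (hemizygous calls from a mixed-sex panel are not comparable across
samples). Region classification uses the precedence exonic > splicing >
5'UTR > 3'UTR > upstream 1 kb > downstream 1 kb > intronic > intergenic,
with the upstream flank anchored at the transcription start and the
downstream flank at the transcription end, strand-aware. Length
distributions are Gaussian KDEs on log10(length >= 50), with modes reported
as local maxima above 5% of the density peak.

# The synthetic-genome generator

`simulate_genome()` plants every structure the analyses look for and returns
the ground truth alongside:

* acrocentric chromosomes: p-arm telomere tract (unit TTAGGG; C-rich strand
  at the p end), a SATVII zone interrupted by SINE/LINE/simple repeats, then
  SATII, SATIV and a SATI/SATVI core whose interspersion encodes
  structure 1 (six alternating blocks) or structure 2 (one changeover);
* an X-like chromosome with a mid-chromosome neocentromere: TE-like
  dispersed copies (a small fixed library pasted with 5–20% per-copy
  divergence — it emulates remnant TE content, not real TE families) and
  high-identity inverted-repeat pairs. All neocentromere material is
  deaminated at the configured rate at the template level, before arm
  copying, so the planted pair identity is controlled independently of the
  CpG signature;
* a tandem rDNA array (ordered 18S/5.8S/28S blocks with uniform-random
  spacers) on the q arm of the first chromosome;
* per-CpG methylation (Beta-distributed around a lower centromeric mean,
  Poisson coverage, two platforms with independent noise) and multi-sample,
  multi-caller SV callsets with configurable sensitivity, false-call rate,
  breakpoint jitter and genotype error.

Background sequence is i.i.d. uniform over the four bases, which makes the
expected-CpG closed forms exact for tests. Every draw is fixed by the config
seed (`withr::with_seed`), so identical configs give byte-identical output.
Truth SVs are annotated but not burned into the sequence — the SV analyses
consume call tables, not alignments. Each truth SV is guaranteed at least two
carrier samples so that the high-confidence filter is attainable at full
sensitivity.

What the simulation does *not* emulate: higher-order repeat structure within
satellite arrays, realistic TE families and ages, read-level error profiles,
and the long-range duplication landscape of a real X centromere. Passing
recovery tests therefore demonstrates correctness of the algorithms under
the planted statistical structure, not performance on real assemblies.

# Problem sizes and numerical choices

The test and acceptance runs use scaled-down study systems chosen to keep
the statistical properties testable: chromosomes of 0.2–1 Mb, centromeres of
50–200 kb, detection windows of 10 kb with the threshold held at the same
1:5 ratio as the 20 kb / 100 kb defaults, 50 simulated chromosomes for
boundary recovery, 100 seeds for methylation power, 500–1000 replicates for
null calibrations, and 10 replicate SV cohorts of 150 SVs × 20 samples ×
4 callers. The Fisher null calibration draws its 2×2 rows from
Binomial(50,000, 0.2): dinucleotide tables in the package's intended use are
built from megabase-scale regions, and at small counts the exact test's
discreteness and conservatism would dominate a uniformity check. Integer-overflow-prone products (`nC * nG` at megabase scale) are
computed in double precision. Degenerate inputs (empty interval sets, empty
compartments, all-tied values, zero-cell tables, regions without CpGs) return
typed empty results, flagged untestable results, or NA ratios rather than
zeros, and each such path is exercised in the test suite.

# Known limitations

* The structure 1/2 transition-count rule is a documented stand-in for a
  visual classification; real assemblies with patchy annotation may land in
  `undetermined`.
* `detect_telomere_tract()` uses fixed-width windows from the terminus; a
  tract interrupted by a long non-telomeric insertion is reported up to the
  interruption.
* The X-centromere span is taken as given (region arguments); the package
  does not claim to delimit a 12 Mb repeat block from a dotplot.
* The exact Mann-Whitney path is limited to groups of 20 windows or fewer
  without ties; above that the mid-rank normal approximation is used.
* `read_annotations()` parses the common column layouts of each dialect, not
  every historical variant; unparseable lines fail loudly with line numbers.
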