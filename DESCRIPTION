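Package: neocent
Title: Centromere, Satellite and Structural-Variant Characterization for
    Telomere-to-Telomere Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing complete (telomere-to-telomere) mammalian
    genome assemblies, motivated by the satellite-free neocentromere of the
    cattle X chromosome. Detects centromere boundaries from windowed satellite
    annotation density and classifies centromere structure by satellite
    interspersion; computes CpG observed/expected, CpG:non-CpG and CpG-vs-TpG
    dinucleotide statistics with Fisher exact enrichment tests and a
    cross-centromere observed-vs-expected regression; compares windowed
    methylation between centromeric and non-centromeric compartments
    (Mann-Whitney) and summarizes CENP-A peak signal per satellite family
    (Kruskal-Wallis); filters and summarizes inverted-repeat pairs, tandem
    repeat units and complete rDNA (18S/5.8S/28S) units; computes assembly
    completeness metrics (N50, gaps, telomere tracts, T2T classification);
    identifies newly annotated genes by annotation complement; and builds a
    multi-caller, multi-sample structural-variant consensus with
    genotype-priority resolution and genomic-region classification. A
    synthetic-genome simulator with ground truth supports recovery testing of
    every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
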