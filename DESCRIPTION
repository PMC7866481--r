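Package: rnaends
Title: Nucleotide-Resolution Detection of Differential RNA Ends in
    Bacterial RNA-Seq
Version: 1.0.0
Authors@R:
    person("rnaends", "maintainers", email = "rnaends@example.org",
           role = c("aut", "cre"))
Description: Detects RNA 3' (or 5') ends at nucleotide resolution from
    strand-specific bacterial RNA-seq alignments and tests them for
    differential abundance between conditions, e.g. a ribonuclease
    mutant versus wild type. Per-nucleotide read-terminus coverage is
    filtered by minimal end coverage and by the ratio of end to full
    coverage, normalized with median-of-ratios size factors, tested
    position-wise with a negative-binomial Wald test under
    Benjamini-Hochberg FDR control, and significant positions are merged
    into differential ends that are assigned to annotated features.
    Additional components compare end sets between two mutants (windowed
    matching, fold-change quadrants, Fisher's exact overlap enrichment),
    profile untemplated 3' tails from soft-clipped local alignments, and
    simulate complete strand-specific datasets with planted ends for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
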