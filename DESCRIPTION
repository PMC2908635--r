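Package: ProbeSieve
Title: In Silico Scoring and Hybridization Quality Control for Long
    Oligonucleotide Microarray Probes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores candidate 60-mer gene-expression microarray probes
    against an annotated genome using four in silico criteria
    (cross-hybridization identity via a word-seeded ungapped search,
    hairpin self-folding free energy from nearest-neighbor
    thermodynamics, distance from the CDS 3' end, and position relative
    to predicted introns), runs the two-round per-CDS probe selection
    with EST-confirmed intron rescue, re-validates probes after genome
    re-annotation, and applies a three-criterion experimental filter
    cascade (signal-to-noise, replicate coefficient of variation, and
    representative-intensity tests) to two-channel hybridization data
    before electing one final probe per coding sequence.  A
    deterministic synthetic-fixture generator with planted probe
    defects makes every rule testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Microarray, GeneExpression, Preprocessing, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
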