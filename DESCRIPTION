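Package: sorfConstraint
Title: Mutational Constraint Scoring for Short Open Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes observed/expected upper-bound fraction (OEUF) constraint
    scores for short open reading frames (sORFs) and neighbouring genomic
    elements from a reference sequence, BED12 sORF definitions and a variant
    site table. Variant consequences are classified natively in the sORF
    reading frame, expected counts come from a trinucleotide-context,
    methylation-aware mutation-rate model, and observed/expected bounds are
    derived with a Poisson grid procedure (SNVOEUF, MOEUF, LOEUF). Includes
    decile-based constraint cut-offs, a frame-respect comparison of missense
    versus all-SNV constraint, regional UTR constraint, score-track matching
    (per-kilobase constraint z-scores, per-base conservation scores),
    rank-based effect-size statistics, and a synthetic-data generator that
    emulates every input so the whole workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    data.table,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'sequence-model.R'
    'consequence.R'
    'constraint-metrics.R'
    'group-stats.R'
    'io-sorfs.R'
    'io-tracks.R'
    'io-variants.R'
    'mutation-model.R'
    'observed-counts.R'
    'synthetic.R'
    'pipeline.R'
    'track-match.R'
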