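Package: guideForge
Title: CRISPR Guide RNA Design with Degenerate PAMs, Off-Target Counting
    and Paired Nickases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates CRISPR target sites for arbitrary effectors
    (degenerate IUPAC PAMs anchored 5' or 3' of the protospacer, custom
    guide lengths), scores them for GC content, PAM-proximal G,
    self-complementarity stems and pluggable position-feature efficiency
    models, counts genomic off-targets at bounded Hamming distance with a
    seed-pigeonhole index, pairs Cas9 nickase sites in PAM-out orientation
    within an offset window and evaluates their paired off-targets, and
    annotates ranked designs with restriction sites and flanking primers.
    Includes a deterministic synthetic-fixture generator for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'iupac.R'
    'seqio.R'
    'accessory.R'
    'effectors.R'
    'enumerate.R'
    'fixtures.R'
    'offtarget.R'
    'nickase.R'
    'scoring.R'
    'report.R'
    'pipeline.R'
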