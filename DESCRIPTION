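Package: azohgt
Title: Taxonomic-Neighborhood Classification of Gene Ancestry and
    Horizontal Transfer in Azospirillum Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies protein-coding genes as ancestral or horizontally
    transferred with tiered confidence from the taxonomic composition of
    their top BLAST hits, using rank-based neighborhood rules anchored on
    the Rhodospirillaceae family and Rhodospirillales order. Includes
    downstream summaries (ancestry proportions, COG functional-category
    enrichment, best-hit donor taxonomy, a 16S rRNA molecular-clock
    divergence estimate), spectral-count proteomics post-processing
    (charge-aware PSM filtering, reverse-decoy false-positive rate, NSAF
    relative abundance), genome-record statistics with in-silico PCR, a
    chemotaxis CheA class assigner, and seeded synthetic-data generators
    that make every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, Proteomics, Classification
RoxygenNote: 7.3.3
Collate: 
    'azohgt-package.R'
    'AllClasses.R'
    'ancestry-batch.R'
    'ancestry.R'
    'blast-io.R'
    'chemotaxis.R'
    'genome-io.R'
    'genome-stats.R'
    'oracle.R'
    'proteomics.R'
    'psm-io.R'
    'simulate.R'
    'summaries.R'
    'taxonomy-io.R'
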