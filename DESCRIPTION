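Package: viroscope
Title: Viral Metagenome Reconstruction and Bits-Per-Base Taxonomic Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers and classifies viral genomes from metagenomic sequence
    data. Implements read recruitment against candidate viral genomes with
    score-radius alignment filtering and Jaccard redundancy removal, naive
    pileup reconstruction of nucleotide and protein database entries into
    per-genome super-scaffolds with CDS-coordinate tiling of protein evidence,
    an iterative contig merge/remap/reassemble improvement cycle, and a
    two-pass bits-per-base taxonomic classifier with a dynamic-radius,
    volume-weighted rank-wise lowest-common-ancestor engine. A synthetic-world
    generator produces internally consistent taxonomies, genomes, reads and
    alignments so the whole pipeline runs and is testable without any
    database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
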