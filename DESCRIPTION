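Package: mitomine
Title: Characterization Analytics for Annotated Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the desk-side characterization of an
    annotated circular mitochondrial genome: circular-coordinate junction
    arithmetic (intergenic spacers and gene overlaps), per-class base
    composition with AT/GC skew statistics, start/stop codon typing, codon
    usage and relative synonymous codon usage (RSCU) under a pluggable
    genetic code (default: invertebrate mitochondrial, transl_table 5),
    signed circular gene-order comparison against ancestral arrangements,
    control-region mining (tandem repeats, microsatellites, homopolymer
    stretches, replication-origin motifs, stem-loop candidates), and
    concatenated supermatrix preparation for downstream phylogenetics.
    Includes a synthetic mitogenome generator with an exact ground-truth
    manifest so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
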