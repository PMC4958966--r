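Package: hgtscreen
Title: Screening Transcriptomes for Horizontally Transferred hAT Transposase Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises horizontally transferred hAT-family
    DNA-transposase genes in parasitic-plant transcriptomes. Implements a
    three-step alien score-ratio screen (host-contamination exclusion by
    pre-attachment expression, open-reading-frame length filtering, and a
    taxon-partitioned bitscore ratio with a nucleotide-level closest-relative
    filter), a target-site-duplication / terminal-inverted-repeat border
    structure search with a brute-force verification oracle, pseudogene
    calling from premature stop codons and frameshift indels, flanking-gene
    synteny comparison, and FPKM / comparative-CT expression summarisation.
    A synthetic-data generator with a ground-truth manifest makes every
    pipeline stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
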