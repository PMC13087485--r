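Package: rdnaquant
Title: Quantification of Uniparental rDNA Silencing in Allopolyploids
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify subgenome-specific expression and dosage of
    ribosomal RNA genes (5S and 26S rDNA) in allopolyploid plants from
    high-throughput sequencing reads. Parental reference units are compared
    to derive diagnostic SNPs; short reads are mapped with an exact local
    aligner under fixed score and acceptance thresholds; homeologous
    transcript and genomic pools are attributed to subgenomes both by
    pooled diagnostic-allele counts and by neighbor-joining classification
    of reconstructed 5S variants under Jukes-Cantor distances, with a
    modified Nei haplotype diversity. Genome proportion of mapped reads is
    converted to rDNA copy number per 1C, and long reads are scanned for
    tandem 5S arrays to estimate monomer periodicity and parental family
    composition. A synthetic-data generator with a ground-truth manifest
    emulates the two-variant 5S system of Cardamine allopolyploids for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
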