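Package: fleshmap
Title: Locus Discovery and CAPS Marker Design for Watermelon Flesh Colour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Pipeline for mapping the two-locus genetic control of canary
    yellow versus incomplete canary yellow flesh colour in watermelon from
    resequencing-style genotype matrices. Implements read-rate genotype
    classification and consensus imputation, a bulked-contrast SNP filtering
    cascade between inbred-line groups, sliding-window candidate-region
    detection, variant effect annotation against gene models, CAPS/dCAPS
    marker design by restriction-site scanning, F2 segregation testing and
    two-point linkage mapping with the Kosambi function, and a two-locus
    epistasis model predicting flesh phenotype from marker genotypes. A
    synthetic-data generator produces genotype panels with planted
    diagnostic regions, toy genomes and gene models, and simulated F2
    populations with known truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
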