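Package: tetrassoc
Title: Candidate-Gene Association Analysis for Autotetraploid Potato
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tetraploid allele-dosage genotyping from Sanger peak-height
    ratios, marker-trait association by one-way dosage-class analysis of
    variance with percent variance explained and direction-of-effect
    reporting, chi-square linkage disequilibrium testing with
    false-discovery-rate correction and LD-block grouping, clone-consensus
    SNP calling for cDNA alleles, haplotype-matrix operations, and a
    synthetic-population generator that emulates the data structure of
    candidate-gene association studies in autotetraploid potato.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
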