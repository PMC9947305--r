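Package: beetol
Title: Heritability and CYP9Q Haplotype Analysis of Clothianidin Tolerance in Honeybees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study the genetics of neonicotinoid tolerance in
    polyandrous honeybee colonies. Simulates queen-drone-worker colonies with
    patriline-structured survival, reconstructs patrilines from multilocus
    microsatellite genotypes by deducing the queen genotype and clustering
    paternal haplotypes, estimates broad-sense heritability of 24-hour
    survival from a nested binomial deviance partition, calls amino-acid
    haplotypes of the CYP9Q detoxification genes from aligned coding
    sequences, and associates haplotypes with survival through weighted
    binomial models and a classification tree with cost-complexity pruning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
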