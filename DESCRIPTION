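Package: canidassign
Title: Forensic Validation of a Diallelic SNP Panel for Wolf and Dog
    Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to validate small panels of ancestry-informative
    diallelic SNP markers for forensic discrimination of grey wolf
    (Canis lupus) from domestic dog (C. l. familiaris). Bundles the
    published wolf/dog genotype and allele frequency database for a
    12-SNP panel, simulates reference and query individuals from
    population genotype frequencies, computes per-locus descriptive
    statistics and Nei's Gst, measures intra- and inter-population
    Euclidean genetic distance separation, and estimates assignment
    accuracy and membership probability by Monte-Carlo and K-fold
    cross-validation with naive Bayes and linear discriminant
    classifiers, plus blind-test assignment of query genotypes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'assignment.R'
    'distance.R'
    'marker-stats.R'
    'panel-data.R'
    'panel-io.R'
    'simulate.R'
    'validation.R'
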