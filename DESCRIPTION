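Package: barcodeAudit
Title: Contamination Screening and Misidentification Audits for COI DNA Barcodes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens cytochrome c oxidase subunit I (COI) DNA-barcode records
    for non-target origin: bacterial and fungal contaminants amplified by
    "universal" Folmer primers, nuclear mitochondrial pseudogenes (numts)
    carrying frame-disrupting indels and internal stop codons, and records
    deposited under the wrong metazoan species. Provides six-frame translation
    integrity checks under mitochondrial genetic codes, Nei-Kumar p-distance
    classification with pairwise deletion, UPGMA-based domain bipartition
    checks, and a binomial sampling design for estimating the prevalence of
    misidentified records in a sequence database (detection probability,
    required sample size, exact Clopper-Pearson intervals, beta-posterior
    record counts and predictive beta-binomial simulation). A seeded synthetic
    database generator with a truth table makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, QualityControl, Classification, Bayesian
RoxygenNote: 7.3.3
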