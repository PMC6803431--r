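Package: hybridase
Title: Allele-Specific Expression and Regulatory Divergence Analysis for
    F1 Hybrid Fish
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the expression of a candidate gene in an
    interspecific F1 hybrid and its two parental pure lines: delta-delta-Ct
    relative quantification of qPCR data, midparent-value based classification
    of the inheritance mode of hybrid expression (additive, dominant,
    overdominant), fixed-difference SNP discovery between parental cDNAs with
    signed primer and amplicon coordinate arithmetic, pyrosequencing based
    allele-specific expression tests with beta-binomial count simulation,
    growth-trial metrics, and the decomposition of parental expression
    divergence into cis and trans regulatory components. A seeded
    synthetic-data generator emulates a two-line tilapia hybridization study
    design so every stage of the pipeline can be exercised and validated
    without access to the original animals.
License: MIT + file LICENSE
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    car,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
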