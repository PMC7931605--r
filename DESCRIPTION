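Package: binqtl
Title: Bin Maps, Linkage Maps and QTL Scans for Low-Coverage F2 Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds recombination-bin genotype maps for F2 mapping populations
    from low-coverage whole-genome resequencing: parent-informative SNP
    selection from VCF, hidden Markov model imputation of genotype blocks from
    per-marker allele depths, crossover calling, genome-wide bin construction,
    Kosambi-scaled linkage maps, gametic and zygotic segregation-distortion
    scans, permutation-thresholded composite-interval QTL mapping, and
    GradedPool-Seq Ridit mapping from phenotype-ranked pools. Includes a
    seeded F2 population simulator with ground truth for parameter-recovery
    and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
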