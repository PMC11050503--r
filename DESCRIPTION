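Package: sweepscan
Title: Selection-Signature Scanning in Multi-Population Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects footprints of selection in multi-population diploid
    genotype data. Implements windowed Weir-Cockerham FST with genome-wide
    Z-standardisation and top-fraction outlier blocks, the FLK test of
    allele-frequency differentiation under a population tree (with a
    permutation-calibrated haplotype-cluster window analogue), consecutive-run
    detection of runs of homozygosity with FROH and ROH islands, within- and
    between-population diversity statistics (observed and unbiased expected
    heterozygosity, rarefied allelic richness, bootstrap FIS, relationship
    matrix PCA), a multi-evidence consensus region caller and gene/QTL
    interval annotation. Ships a seeded Balding-Nichols synthetic-data
    generator with implanted sweeps and autozygous tracts so the whole
    pipeline is testable against a known truth set.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    cluster,
    vcfR,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
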