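Package: bdellometh
Title: Simulation and Analysis of 4mC/6mA DNA Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for analysing N4-methylcytosine (4mC) and
    N6-methyladenine (6mA) DNA methylomes of the kind found in bdelloid
    rotifers: single-base modification calling from single-molecule
    polymerase kinetics (IPD ratios) with coverage and quality filters,
    per-site methylation-fraction estimation and classification, DIP-seq
    and ChIP-seq coverage normalization (RPGC, log2 IP/input) and global
    Poisson enrichment peak calling, feature-association statistics
    (normalized densities, occupancy profiles and metaprofiles, windowed
    intersections, Jaccard spatial correlation with permutation nulls,
    transposon-integrity stratification, chromatin co-localization,
    RPKM expression grouping), and sequence-context statistics
    (doublet/triplet composition, k-mer Fisher enrichment). A synthetic
    annotated-genome and methylome generator with simulated kinetics and
    read sets makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
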