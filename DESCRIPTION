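Package: popgenscan
Title: Population-Genomic Divergence Scans, f4 Admixture Tests and
    Isolation-by-Distance for Reduced-Representation SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of biallelic SNP matrices
    from reduced-representation sequencing (e.g. RAD-seq) mapped to a
    reference with named linkage groups. Implements quality masking and site
    filtering of VCF genotypes, distance thinning, preparation of complete
    unlinked SNP panels with stationary forward/backward mutation rates for
    species-tree inference, linkage-disequilibrium decay profiles with
    cross-linkage-group background, Weir-Cockerham FST and absolute
    divergence (DXY) in sliding and nonoverlapping genomic windows, the f4
    four-population admixture test with weighted block-jackknife standard
    errors and high-precision normal tail p-values, empirical top-quantile
    FST outlier windows with a modified nearest-neighbour-index permutation
    test for genomic clustering, Vincenty geodesic distances and Mantel
    tests of isolation by distance, and a seeded synthetic-data generator
    (Balding-Nichols drift with optional admixture pulses and
    distance-limited linkage disequilibrium) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    geosphere,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
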