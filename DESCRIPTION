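Package: hybridils
Title: Two-Locus Hybrid Incompatibility Genetics and ILS-vs-Introgression Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the population genetics of duplicate-gene-loss hybrid
    incompatibility in rice. Implements a sex-specific gamete-elimination model
    for distorted F2 segregation at a duplicated gene pair (expected genotype
    frequencies, chi-square goodness of fit, maximum-likelihood transmission
    parameter estimation, and cross-compatibility prediction from allele
    classes), Nei-Gojobori (1986) synonymous/nonsynonymous divergence with
    Jukes-Cantor correction and Ks-peak divergence dating (T = Ks/2*lambda),
    distance-based quartet topology calls with a coalescence-time rule
    discriminating incomplete lineage sorting from introgression, Patterson's D
    and windowed fd statistics with block-jackknife significance and top-0.5%
    outlier calling, sliding-window nucleotide diversity, pairwise LD r2 and
    one-degree-of-freedom allelic case/control association, plus seeded
    synthetic-data generators for every stage so the whole pipeline is testable
    without external genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
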