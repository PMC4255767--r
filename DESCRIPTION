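Package: hapsweep
Title: Selective-Sweep Scanning from Phased Haplotypes with Empirical
    Calibration
Version: 0.1.0
Authors@R: person("hapsweep", "maintainers", email = "hapsweep@example.org",
    role = c("aut", "cre"))
Description: Intraspecific positive-selection scan for phased diploid
    variation data. Implements site-frequency-spectrum estimators
    (nucleotide diversity, Watterson's theta, Tajima's D, Fay and Wu's H
    with Zeng normalization) over gene regions and sliding windows,
    per-SNP Weir-Cockerham F_ST with minor-allele-frequency-binned
    empirical percentile ranking, the DIND (Derived Intra-allelic
    Nucleotide Diversity) test with derived-allele-frequency-binned
    calibration and sentinel handling, linkage-disequilibrium r2 and
    haplotype-matrix reports, and a combined-evidence caller that flags a
    region as a selection target when at least two statistics from
    different feature families are empirical outliers in the same
    population. A coalescent simulator (neutral equilibrium, two-deme
    island model, hard-sweep approximation by intra-allelic time
    compression) generates phased, polarized cohorts in standard formats
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    data.table,
    optparse,
    jsonlite
Config/testthat/edition: 3
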