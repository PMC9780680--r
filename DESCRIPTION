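Package: altiscan
Title: Selection-Signature Scans for Altitude-Contrast Population Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Haplotype- and allele-frequency-based genome scans for positive
    selection in a three-population design (a focal population pair plus an
    outgroup), as used to contrast highland and lowland cattle populations.
    Implements extended haplotype homozygosity (EHH) and the standardized
    integrated haplotype score (iHS) with frequency-bin standardization and a
    normal-tail p-value transform; the cross-population composite likelihood
    ratio (XP-CLR) sweep test; per-site and windowed Weir-Cockerham and Hudson
    FST; the population branch statistic (PBS); windowed nucleotide diversity;
    pairwise linkage-disequilibrium matrices with haplotype-block calling; and
    the sliding-window, outlier-calling, region-merging, intersection and
    gene-annotation logic that turns per-SNP statistics into candidate gene
    lists. A compiled forward Wright-Fisher simulator with recombination and a
    hard selective sweep generates phased data with known ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
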