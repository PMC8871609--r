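Package: colpopgen
Title: Population-Genetic Selection Signatures at a Collagen Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diversity, differentiation, linkage-disequilibrium, conservation
    and haplotype-age analyses for a COL1A1-like collagen locus in humans and
    chimpanzees. Implements Watterson's theta, per-SNP Hudson F_ST with a
    pooled-resampling outlier scan, pairwise r2 linkage disequilibrium with
    minor-allele-frequency filtering, the McDonald-Kreitman test,
    length-weighted intron conservation randomization, a spatial clustering
    test for fixed differences, two-medoid haplogroup partitioning,
    neighbor-joining trees, and the Thomson moment estimator of haplogroup
    age, together with a synthetic-data generator (stem-and-star genealogies,
    Balding-Nichols population pairs, block-structured conservation tracks,
    severity-stratified mutation catalogs) that emulates the statistical
    structure of the real inputs so the full battery runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    seqinr,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
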