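Package: fragpop
Title: Genetic Monitoring of Fragmented Riverine Fish Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SNP-based genetic monitoring of small, fragmented
    populations: quality-control filtering of reduced-representation SNP
    genotypes, individual and population heterozygosity and effective
    inbreeding, single-sample linkage-disequilibrium (Burrows composite)
    estimation of the effective number of breeders with life-history
    adjustments for iteroparous species, genetic-rescue migrant calculators,
    PCA-based ancestry classification, Weir-Cockerham FST and Mantel
    isolation-by-distance, relatedness-based sibship surrogates, Gompertz
    growth models with an inbreeding-depression model ladder, and a
    Wright-Fisher metapopulation simulator with riverine barriers and
    translocation used to validate every estimator against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
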