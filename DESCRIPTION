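Package: haplopop
Title: Population Genetics of Haploid Multilocus Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for haploid multilocus microsatellite (SSR)
    genotypes with mating-type annotations, aimed at fungal and other
    haploid organisms sampled across hierarchically structured landscapes.
    Implements Nei's unbiased haploid diversity, rarefaction-standardized
    allelic and private allelic richness, multilocus linkage disequilibrium
    (index of association and rBarD) with permutation tests, hierarchical
    distance-based AMOVA with Phi-statistics and pairwise FST, discriminant
    analysis of principal components (DAPC) with BIC cluster selection,
    isolation-by-distance Mantel tests on Edwards' chord distances, spatial
    analysis of shared alleles (SAShA), and detection of geographically
    restricted alleles by centroid bootstrap. A hierarchical island-model
    simulator generates synthetic datasets with known truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
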