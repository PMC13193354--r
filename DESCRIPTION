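Package: hierstock
Title: Hierarchical Mixed-Stock Analysis of Multiallelic Codominant Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting nested genetic population structure in
    mixed stocks genotyped at multiallelic codominant markers such as
    microsatellites. Provides GenePop and CSV input/output with allele
    binning from raw fragment lengths, within-sample diversity statistics
    (heterozygosities, inbreeding coefficient, polymorphic information
    content, rarefied and jackknife allelic richness), exact
    Hardy-Weinberg and genotypic linkage-disequilibrium tests with
    sequential Bonferroni control, differentiation statistics (Jost's D,
    Hedrick's G''ST, two-level AMOVA on squared genotype distances) with
    permutation and resampling uncertainty, maximum-likelihood mixture
    and admixture clustering with simulated annealing and EM,
    log-likelihood-curvature K selection, and a recursive order-by-order
    decomposition that uncovers hierarchically nested demes. A seeded
    generator of nested-deme genotype data under the Balding-Nichols
    drift model supports calibration and recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
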