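Package: invabc
Title: Invasion-History Inference by Coalescent Simulation and Approximate
    Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the invasion history of serially
    sampled populations from microsatellite genotypes and mitochondrial
    sequence data. Provides a multi-population serial-sample coalescent
    simulator with generalized stepwise (microsatellite) and HKY
    (mtDNA) mutation models, declarative demographic scenarios with
    parameter priors, DIYABC-style summary statistics, and an
    approximate Bayesian computation engine for scenario choice
    (logistic posterior probabilities with confidence intervals and
    type I/II error rates), parameter estimation (local-linear
    regression adjustment), and model checking (PCA of summary
    statistics). Companion statistics for characterising
    spatio-temporal structure are included: diversity summaries,
    pairwise differentiation (Weir-Cockerham theta, Jost's D, G''ST,
    PhiPT) with permutation significance, Mantel tests, bottleneck
    detection (Garza-Williamson M-ratio and the heterozygosity-excess
    test under a two-phase mutation model), and mtDNA haplotype
    analysis (haplotype collapsing, diversity, Tajima's D,
    minimum-spanning haplotype networks).
License: GPL (>= 3)
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
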