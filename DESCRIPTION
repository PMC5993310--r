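Package: hwclust
Title: Fast Maximum-Likelihood Genetic Clustering and Hybrid Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast maximum-likelihood assignment of individual multilocus
    genotypes to panmictic populations under a Hardy-Weinberg multinomial
    likelihood, optimised by a hard-assignment (classification) EM algorithm
    with Ward, K-means or multi-start random initialisation. Optionally
    detects hybrid classes (F1, backcrosses) between two parental populations
    via mixture allele frequencies parameterised by a hybridisation
    coefficient, and guides the choice of the number of clusters with AIC,
    AICc, BIC and KIC. Includes readers and writers for Genepop, STRUCTURE,
    allele-count CSV and biallelic VCF genotypes, a Balding-Nichols
    population simulator with island and stepping-stone differentiation,
    hybrid-cross simulation, a multilocus Weir-Cockerham Fst estimator, and
    pairwise TPR/TNR clustering evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
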