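Package: musselmix
Title: Hybrid Zone Analysis for Blue Mussels from Partially Diagnostic Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bimodal hybrid zones between Mytilus edulis
    and Mytilus trossulus (and similar two-taxon systems) from small panels of
    partially diagnostic co-dominant loci. Implements compound-allele pooling
    and hybrid indices (T-scores, scaled T-frequencies), genotypic
    disequilibrium statistics (heterozygote deficit and composite inter-locus
    correlation) with their theoretical maxima under non-interbreeding
    mixture, Monte-Carlo goodness-of-fit tests of T-score distributions, a
    two-population Bayesian admixture model (Gibbs sampler) yielding
    individual and sample ancestry scores, simulation of known-ancestry
    genotypes for calibrating purebred/hybrid assignment thresholds, shell
    morphotype scoring and genotype-morphotype concordance, substrate-specific
    density estimation, and a synthetic-study generator exercising the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
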