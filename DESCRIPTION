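Package: pedppl
Title: Posterior Probability of Linkage Analysis in Extended Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-point parametric linkage analysis of extended, loop-free
    pedigrees using the posterior probability of linkage (PPL) framework.
    Implements exact Elston-Stewart pedigree likelihoods under dichotomous,
    quantitative, and quantitative-threshold trait models with Smith's
    admixture (heterogeneity) parameter, integration of trait parameters
    under ordered-uniform priors to per-pedigree Bayes ratios, and both
    pooled and sequentially updated accumulation of linkage evidence across
    pedigrees. Includes readers for pre-makeped LINKAGE pedigree files and
    genetic maps, the standard genotype quality-control filters (marker and
    sample missingness, Mendelian-error detection, Hardy-Weinberg testing,
    LD thinning), scoring and sex-specific classification of the Broad
    Autism Phenotype Questionnaire together with dichotomous, quantitative
    and threshold-censored trait codings for autism-related phenotypes, and
    a gene-dropping simulator of ascertained multiplex pedigrees for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
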