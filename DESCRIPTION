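Package: genoscore
Title: Odds-Ratio-Weighted Genetic Scores for Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A case-control pipeline for SNP-based genetic risk scores:
    per-SNP association screening (allelic odds ratios, Hardy-Weinberg exact
    test, Fisher's exact test for rare alleles, Bonferroni correction),
    construction of multiplicative genetic scores in which each genotype's
    risk is normalized to the population-average risk so that the score has
    population mean one, linkage-disequilibrium-based pruning of redundant
    SNPs, risk stratification with Cochran-Armitage trend tests, and ROC/AUC
    evaluation with DeLong or Hanley-McNeil confidence intervals.  Includes
    a case-control genotype simulator (Hardy-Weinberg sampling, two-locus
    haplotypes at a target r-squared, a logistic disease model with
    rejection sampling) so every stage can be exercised end to end on
    synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, pROC, vcfR, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
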