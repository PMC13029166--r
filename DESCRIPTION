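Package: pathgrs
Title: Pathway-Based Genetic Risk Scores for Blood Lipid Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and evaluation of pathway-based genetic risk
    scores (GRS) for triglyceride and HDL-cholesterol concentrations from
    small targeted SNP panels. Implements per-SNP quality control (minor
    allele frequency, call rate, Hardy-Weinberg equilibrium), linkage
    disequilibrium estimation from unphased genotypes (EM-based D' and
    composite r-squared) with tag-SNP pruning, per-SNP general linear
    models with least-squares means and Tukey-Kramer pairwise comparisons,
    phenotype-specific risk-allele orientation, additive and beta-weighted
    GRS per metabolic pathway with median-split risk groups, GRS-phenotype
    association models with partial R-squared variance decomposition,
    ancestry-informative-marker principal components for admixture
    adjustment, and a synthetic cohort generator that emulates the
    statistical structure the analysis assumes so the whole pipeline is
    testable without access to individual-level study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    emmeans,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
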