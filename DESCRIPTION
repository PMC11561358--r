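Package: sibscore
Title: Polygenic Score Pipelines with Within-Sibling Decomposition of
    Direct and Indirect Genetic Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing polygenic scores (PGS) from GWAS
    summary statistics and genotype dosages (quality control, allele
    harmonization, LD clumping, multi-threshold scoring and PGS-PCA
    aggregation), harmonizing cardiometabolic biomarkers (medication
    adjustment, outlier trimming, log transformation, standardization),
    estimating population-level PGS-outcome associations with
    family-clustered sandwich standard errors and Nagelkerke delta-R2,
    and separating direct from indirect genetic effects with
    within-sibling fixed-effects and conditional logistic models. A
    bundled family-genotype simulator with Mendelian transmission,
    block LD, genetic nurture, shared environment, population
    stratification and assortative mating provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    sandwich,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
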