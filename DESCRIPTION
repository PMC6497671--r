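Package: coachgx
Title: Genetic Predisposition and Longitudinal Clinical-Marker Change in
    Lifestyle Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how genetic predisposition (polygenic scores and
    single SNPs) relates to baseline levels and longitudinal change of clinical
    markers in a lifestyle coaching cohort. Provides pruning-and-thresholding
    polygenic score construction from GWAS summary statistics (Benjamini-Hochberg
    FDR selection, greedy LD pruning, mean imputation of missing genotypes),
    cohort filtering with baseline reference-range stratification, linear mixed
    models with regression splines on continuous time for adjusted 6- and
    12-month changes, gene-by-time interaction models adjusting for baseline,
    partial r-squared variance decomposition, and a synthetic-cohort generator
    (LD-blocked genotypes, internally consistent summary statistics, irregular
    visit times, medication and fasting exclusions) so every stage is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
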