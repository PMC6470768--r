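Package: lactomics
Title: Multi-Block Chemometric Analysis of Preterm Breast-Milk Omics and
    Infant Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline linking preterm breast-milk composition
    (metabolome, lipidome, glycome, free amino acids, fatty acids) to early
    infant growth: quality-control RSD feature filtering, log-Pareto and
    autoscaling, ANOVA-PLS discriminant analysis with Fisher LDA and
    leave-one-out validation, VIP-based feature selection, Mann-Whitney
    screening with Benjamini-Hochberg false-discovery-rate control,
    confounder-adjusted multiple linear regression of growth on candidate
    biomarkers, and multi-block PLS / unfold-PCA fusion of the omics blocks.
    Includes a synthetic cohort generator emulating a two-growth-group
    mother-infant dyad study with twins, maternal secretor status, pooled
    quality-control replicates and planted discriminant features, so the
    whole workflow is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
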