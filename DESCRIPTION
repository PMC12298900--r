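Package: fishmerc
Title: Fish Mercury Meta-Database Reconstruction and Dietary Exposure Risk for the Amazon Basin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing mercury contamination in Amazon-basin fish and
    human exposure through fish consumption. Provides a report-level data model
    for literature-extracted mercury summaries (mean, SD, n of muscle Hg plus
    ecological covariates), a seeded synthetic-database generator with known
    effect structure, meta-analytic reconstruction of individual-level
    pseudo-observations from summary statistics, a linear-model suite (Box-Cox
    transform selection, one-way ANOVA with Tukey-Kramer comparisons and
    compact letter displays, size regressions, type III sum-of-squares partial
    R-squared), and a deterministic plus probabilistic (one-dimensional Monte
    Carlo) estimated-weekly-intake risk engine compared against the JECFA
    provisional tolerable weekly intake, with a closed-form log-normal oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    car,
    sandwich,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
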