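Package: polystrat
Title: Polygenic Adaptation Tests and Stratification Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing polygenic adaptation from GWAS summary
    statistics and population allele frequencies, and for diagnosing how
    uncorrected population stratification in effect-size estimates creates
    spurious adaptation signals. Implements population-level polygenic
    scores with Beta-posterior credible intervals, the Qx overdispersion
    test and a latitude-cline test under a multivariate-normal drift null,
    trait-aligned singleton density score (tSDS) trend analysis with
    block-jackknife errors, LD-based SNP ascertainment (lowest-P-per-block,
    greedy clumping, and r-squared pruning), and stratification diagnostics
    based on principal-component SNP loadings and two-population frequency
    contrasts. A seeded synthetic-data generator produces allele-frequency
    drift, confounded GWAS effect estimates, SDS-like scores and genotype
    panels with known ground truth, so every test in the stack can be
    calibrated against its null and its power mechanisms verified.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
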