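Package: methvc
Title: Genetic and Environmental Variance Decomposition of DNA Methylation
    in Twin Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-site decomposition of DNA methylation variance into genetic
    and environmental components in twin-family designs. Implements classical
    ACE/ADE twin models with likelihood-ratio tests, the Falconer estimate,
    a two genetic-relationship-matrix (GRM) mixed model separating
    SNP-tagged from total additive genetic variance, and variance-moderation
    (genome-by-age, genome-by-sex) interaction models with Wald chi-square
    tests. Includes Illumina-450k-style beta/M value transforms, probe and
    sample quality-control filters, covariate residualization, CpG-island
    and gene-region annotation with chi-square enrichment tests,
    longitudinal and cross-tissue summaries, and a synthetic twin-family
    methylome generator with known ground truth for validating every
    estimation stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
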