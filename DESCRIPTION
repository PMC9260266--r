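Package: msapr
Title: Methylation-Sensitive Amplified Polymorphism (MSAP) Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for methylation-sensitive amplified
    polymorphism (MSAP) data. Classifies HpaII/MspI band profiles into the
    four CCGG methylation patterns (I-IV), computes total, hemi- and full
    methylation levels, types control-versus-treatment pattern changes into
    methylation-gain (B1-B4) and demethylation (C1-C4) events, computes gene
    co-occurrence rates from presence/absence matrices, and provides the
    supporting quantitation used in methylation studies: 2^-ddCt relative
    expression, 5-methylcytosine percentage from chromatogram peak areas, and
    one-way ANOVA followed by Duncan's multiple range test with compact
    letter display. A seeded simulator generates MSAP datasets with known
    per-locus methylation states and a dose-dependent demethylation model so
    every stage of the pipeline can be validated against ground truth.
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
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
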