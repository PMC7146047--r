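Package: snpmeta
Title: Genetic Association Meta-Analysis from Genotype Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control genetic association meta-analysis computed directly
    from study-level genotype counts. Builds the five classical genetic-model
    contrasts (allelic, heterozygote, dominant, homozygote, recessive), screens
    control groups for Hardy-Weinberg equilibrium, pools odds ratios with the
    Mantel-Haenszel fixed-effect estimator (Robins-Breslow-Greenland variance)
    or DerSimonian-Laird random effects selected by the Cochran Q heterogeneity
    test, and runs Egger regression and Begg-Mazumdar rank-correlation
    publication-bias tests plus leave-one-out sensitivity analysis. Ships a
    fully worked case-control data set on complement factor I (CFI)
    polymorphisms and age-related macular degeneration, and a synthetic-study
    generator for property testing. All user-facing functions take data frames
    and return tibbles.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
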