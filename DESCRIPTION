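Package: stomataWUE
Title: Stomatal Trait Derivation, Association Scans, and Ball-Woodrow-Berry
    Modeling for Sorghum Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for water-use-efficiency phenotyping of a
    sorghum diversity panel. Derives stomatal anatomical traits (density,
    size, maximum pore area, pore area per leaf area, and anatomical maximum
    stomatal conductance) from leaf-impression measurements; adjusts
    plot-level field phenotypes with a REML random-intercept mixed model;
    runs a principal-component-adjusted single-marker genome-wide
    association scan with Bonferroni thresholding and candidate-gene window
    extraction; groups accessions into multi-locus haplotype classes with
    one-way ANOVA and Tukey HSD compact-letter comparisons; and fits the
    Ball-Woodrow-Berry stomatal conductance model to light-response curves
    under contrasting water regimes. A seedable synthetic-data generator
    emulates the genotype, field-design, impression, and gas-exchange
    structure of the panel so every stage is testable without the original
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    vcfR,
    ape,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
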