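Package: famnet
Title: Family-Based Gene Coexpression Network Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds signed weighted gene coexpression networks separately for
    each family of a pedigree study, tests module eigengenes against
    quantitative traits with kinship-aware variance-components mixed models,
    and combines family-specific modules by highest-overlap matching and
    intersection/union common gene sets. Includes robust biweight
    midcorrelation, topological overlap, module detection, pedigree kinship
    computation, REML estimation with genetic and shared-environment kernels,
    per-probe heritability filtering, two naive whole-sample network baselines,
    a single-probe mixed-model scan, and a synthetic multi-family data
    generator for end-to-end validation.
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
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
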