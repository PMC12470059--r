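Package: direnrich
Title: Direction-Aware Gene-Set Enrichment for Differential-Expression
    Signatures
Version: 0.1.0
Authors@R:
    person("BA9", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for direction-aware integration of differential-expression
    results with curated gene sets. Parses DE export tables, ranks genes by a
    composite score combining effect size and statistical confidence, builds
    fixed-size direction-preserving core signatures, and tests miRNA-target or
    transcription-factor-target sets for over-representation within the up- or
    down-regulated partition of an expressed-gene universe using one-sided
    Fisher exact tests, Haldane-Anscombe-corrected odds ratios with Woolf
    confidence intervals, and Benjamini-Hochberg adjustment within
    pre-specified test families. Includes marker-based sensitivity re-testing
    against composition confounding and a synthetic-data generator with a
    planted membership-direction odds ratio for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
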