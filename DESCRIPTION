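Package: ripchip
Title: Enrichment Calling for RNA Immunoprecipitation Microarray (RIP-Chip) Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel RIP-chip experiments, in which a
    tagged bait protein is immunoprecipitated together with its bound mRNAs and
    the co-purified RNA is hybridised against a total-RNA reference. Provides
    platform-specific spot quality filtering based on per-channel pixel
    fractions, per-gene median log10 enrichment ratios, standardized and
    SD-above-median scores, replicate-intersected target calling with a
    contaminant blacklist and a p^k false-positive estimate, bait
    classification (empty / bait-only / targets), perturbation scoring
    (-ATG, puromycin, EDTA) with P/ND codes and lost/retained verdicts, and a
    seeded spot-level simulator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
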