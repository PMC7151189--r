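Package: distractr
Title: Distractor Analysis Effect Sizes for Multiple-Choice Items
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Item analysis of multiple-choice response data with a focus on
    the ability-related discriminatory power of distractors. Implements
    item-level effect sizes (Cohen's omega over ability-group by distractor
    contingency tables and the canonical correlation between distractor
    choice indicators and non-solver total scores) alongside traditional
    distractor indices (point-biserial contrasts, the Haladyna-Downing
    per-distractor omega, Goodman-Kruskal gamma for rising selection ratios,
    and the 5 percent choice-frequency screen). Includes a two-parameter
    nested logit (2PNL) response simulator combining a 2PL solution model
    with a nominal response model for distractor choice, and a Monte-Carlo
    study harness to estimate type-I error and power of the effect sizes
    across design cells, with a command-line interface for simulation,
    analysis, and study runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
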