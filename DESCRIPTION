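Package: psefit
Title: Assessing Language-Model Fit to Patient Safety Event Report Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven pipeline for assessing how well candidate language
    models fit the free text of patient safety event (PSE) incident reports.
    Selects category-discriminative target tokens by a conditional-probability
    dominance rule, extracts a minimal covering set of target sentences under a
    one-sentence-per-report constraint via greedy depth-first search with
    backtracking, scores each target sentence's perplexity under pluggable
    language-model backends (a reference additive-smoothed n-gram model is
    included), and compares models per event category with one-way ANOVA and
    mean/SEM summaries. A seeded synthetic-corpus generator with planted
    category-specific vocabulary makes every stage testable without access to
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
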