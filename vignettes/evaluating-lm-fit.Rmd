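---
title: "Evaluating language-model fit to incident-report text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating language-model fit to incident-report text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psefit)
```

## The problem

Hospitals collect large volumes of free-text patient safety event (PSE)
reports — short narratives of falls, medication errors, conduct issues and
similar incidents, written by any member of staff. Before committing to a
language model for analysing such text, one wants a cheap, data-driven answer
to a simple question: *how well does a candidate model "fit" the kind of
language these reports contain, category by category?*

`psefit` implements a four-stage strategy for answering it:

1. **Target tokens.** For every analysis token $t$ and event category $n$,
   estimate the conditional probability $p(t \mid n)$. Token $t$ becomes a
   *target token* of category $j$ when
   $$p(t \mid n_j) \;>\; \sum_{k \ne j} p(t \mid n_k),$$
   i.e. when more than half of the token's total conditional mass sits in one
   category. This strict-dominance rule makes the per-category sets pairwise
   disjoint by construction. An expert-review filter (file-driven deny/allow
   lists) then removes tokens that discriminate for administrative rather
   than clinical reasons.
2. **Target sentences.** For each category, select a minimal set of sentences
   that jointly contain ("cover") all its target tokens, using **at most one
   sentence per report** so no single report dominates the evaluation set.
   This is a constraint-satisfaction problem solved by greedy depth-first
   search with backtracking.
3. **Perplexity.** Score every target sentence under every candidate model:
   $\mathrm{PPL}(s) = \exp\!\big(-\tfrac1n \sum_{i=1}^n \log p(w_i \mid
   w_{<i})\big)$, with a start-of-sequence context so the first token is
   conditionally scored. Lower perplexity means the model finds the text less
   surprising — a better fit.
4. **Comparison.** Per category, report each model's mean perplexity and SEM
   and test for between-model differences with a one-way ANOVA; rank
   sentences by their across-model average perplexity to surface the
   best-fitting narratives.

## Text conventions

The selection stage needs its own deterministic tokenization, independent of
any model's subword vocabulary. The convention (see `tokenize()`): lowercase,
split on runs of non-alphanumeric characters, drop pure-number tokens, keep
tokens of at least two characters. Hyphenated drug names therefore split into
their components, and room numbers or report IDs never become "discriminative"
tokens. No stopword list is applied: ubiquitous words fail the dominance rule
on their own, and the expert filter handles the remainder.

Sentences are segmented by a rule-based, abbreviation-aware splitter
(`segment_sentences()`): boundaries are runs of `.`, `!`, `?` followed by
whitespace, except after a fixed, versioned list of abbreviations ("Dr.",
"Mrs.", ...). A deterministic segmenter matters here because the cover
algorithm's input — and hence its output — must be reproducible.

The estimator behind $p(t\mid n)$ is token relative frequency: occurrences of
$t$ among all tokens of category $n$ divided by the category's token total,
so each category's probabilities sum to one. An alternative reading —
report-level document frequency — is exposed as
`token_stats(corpus, estimator = "report")` for sensitivity analysis; the two
agree on which tokens dominate whenever token counts per report are roughly
homogeneous. A minimum raw count (default 3) filters hapax artifacts that the
rule would otherwise select off a single occurrence.

## The cover algorithm

`solve_cover()` orders candidate sentences by the number of still-uncovered
target tokens they contain (ties broken by `(report_id, sent_index)` for
determinism) and repeatedly takes the best sentence whose report has not been
visited. When uncovered tokens remain but no valid sentence exists — the
remaining tokens live only in already-visited reports — the most recent
selection is reverted, its tokens restored, its report freed, and the next
alternative at that decision point tried. The search is therefore a complete
depth-first traversal in greedy order: if a full cover exists it will be
found; if none exists, the best solution seen is kept. Three policies make
degenerate inputs well defined:

* Tokens contained in no candidate sentence are reported `uncovered` with
  reason `no_candidate_sentence` before the search starts; residual tokens
  that lose out to the one-per-report constraint get reason
  `report_conflict`. Infeasibility is data, not an exception.
* Among distinct maximal-coverage solutions (possible only on infeasible
  instances) the canonical winner is the one whose covered-token set has the
  greatest cardinality, then is lexicographically smallest. The exhaustive
  reference solver `exact_cover()` applies the same rule, then minimizes the
  number of sentences, so the two solvers are comparable property by
  property.
* A node-expansion cap (default 10 000 per category) bounds the search on
  adversarial instances; hitting it freezes the best partial solution and
  flags `cap_hit`. The greedy solution can use more sentences than the
  `exact_cover()` optimum — the method is greedy by design — but never covers
  fewer tokens on instances small enough to enumerate.

## Perplexity backends

Scoring is defined against a minimal backend contract (`lm_backend`): a
tokenizer plus per-token conditional log-probabilities, deterministic for a
fixed model and input, each probability in $(0,1]$. Three backends ship:

* `uniform_backend(V)` and `constant_backend(p)` — closed-form references
  (perplexity exactly $V$, exactly $1/p$) used to validate the scoring path.
* `fit_ngram_backend(texts, order, smoothing)` — the working reference model:
  additive (Lidstone) smoothed n-gram estimates of order 1–3 over the closed
  training vocabulary plus an explicit unknown class, so every conditional
  distribution sums to one and unseen tokens keep perplexity finite. As
  `smoothing` grows the model tends to the uniform distribution over
  vocabulary + unk, which pins its behaviour at both extremes.
* `transformer_backend(checkpoint)` — an optional adapter for causal LM
  checkpoints and their own subword tokenizers, delegating to a bundled
  Python helper (requires `torch` and `transformers`). Its absence never
  affects the rest of the package; the constructor fails with an actionable
  environment error when the runtime is missing.

Two protocol details are configurable but fixed by default: a
start-of-sequence context gives the first token a proper conditional
probability, and sequences longer than the backend's `max_sequence_length`
(1024 by default; checkpoint-dependent for transformers) keep their prefix.
Single target sentences essentially never truncate. Batching
(`batch_score()`, default batch size 16) is bookkeeping only — values are
identical to one-by-one scoring, and a property test enforces that.

## Statistical comparison

`summarize_perplexity()` reports mean and SEM ($s/\sqrt{n}$) per (category,
model) and a one-way fixed-effects ANOVA per category with model as the
factor. The ANOVA runs on raw perplexities by default, matching how such
comparisons are usually reported; because perplexity is right-skewed,
`scale = "log"` switches the test (not the reported means) to log scale.
Sentences are treated as independent observations and no post-hoc pairwise
tests are run — deliberate simplifications; the omnibus p plus the means
carry the interpretation. Degenerate categories (fewer than two models or
two sentences) are summarized without a test. When the between-group sum of
squares is numerically zero the test is reported as $F=0, p=1$ rather than
NaN.

`null_calibration()` exists to validate this wiring, not as a pipeline
stage: under a shared-Gaussian null the p-values must be uniform (checked by
the fraction below 0.05 and a Kolmogorov–Smirnov distance), and under a
planted one-standard-deviation shift at $n = 60$ per group the test must
essentially always reject.

## What the synthetic generator emulates — and what it does not

Real PSE corpora are protected, so the package ships a seeded generator
(`generate_corpus()`) that reproduces exactly the structural features the
pipeline depends on: several categories over a shared vocabulary,
category-specific tokens at elevated frequency, multi-sentence reports, and
full determinism given a seed. Reports are bags of unigrams: category
sampling weights are uniform over a shared vocabulary with each category's
planted signal tokens boosted by a constant factor and renormalized.

Defaults — 4 categories × 200 reports, a 300-token vocabulary, 10 signal
tokens per category boosted 20-fold, ~Poisson(4) sentences of ~Poisson(8)
tokens — were chosen so that planted-token recovery is comfortably powered
at desk scale: at these sizes a category sees ≈ 6 400 tokens, a signal
token's home-category frequency (≈ 0.041) exceeds the sum of its
frequencies elsewhere by a factor of ≈ 6, and the expected number of
background tokens that pass the dominance rule by sampling noise is well
below one. The test suite asserts precision and recall ≥ 0.9 under these
conditions, and a win rate of at least 38/40 for category-matched bigram
models over mismatched ones on held-out sentences — the synthetic stand-in
for the clinical-versus-general model contrast.

What passing these tests does **not** show: anything about real clinical
syntax, misspellings, templated boilerplate, abbreviation load, or
correlations between sentences of one report. The generator produces
exchangeable unigram bags; it validates the machinery (counting, covering,
scoring, testing), not linguistic realism. Conclusions about specific
checkpoints on real reports require running the pipeline on real reports.

A 40-report fixture generated by this same code (seed 12061, 4 categories ×
10 reports, 60-token vocabulary) is bundled under `inst/extdata/` — files
prefixed `synthetic_` — for fast deterministic smoke tests; properties are
tested against freshly generated corpora.

## Numerical and design choices

* Strict inequality in the dominance rule, as stated; exact ties select
  nothing.
* Natural-log internals for perplexity; reported as `exp(mean NLL)`.
* Unknown tokens receive explicit smoothed mass — perplexity stays finite on
  any input.
* Problem sizes in the shipped tests: 1 000 fuzzed count matrices for the
  disjointness property, 300 fuzzed instances (≤ 7 reports) for
  greedy-versus-exhaustive cover comparison, 40 discrimination trials, 500
  null ANOVA replicates. These sizes give the properties high power while
  keeping the default suite quick to run.
* The pipeline couples its stages through flat CSV artifacts so that a
  curated token list can be dropped in between the token and sentence stages
  — the reproducible analogue of the expert-review step.

## Known limitations

* The greedy cover is not guaranteed minimum-cardinality at scale (by
  design; `exact_cover()` is exponential and capped at 10 reports).
* The report-frequency estimator is provided but untested against any
  real-data baseline; the token-frequency default is the primary path.
* ANOVA on raw perplexities inherits the skewness of the metric; for small
  sentence counts per category the log-scale switch is the safer choice.
* The transformer adapter loads the checkpoint per scoring call; it is
  correct but not optimized for large sentence sets.
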