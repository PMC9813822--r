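---
title: "Temporal referrals in radiology reports: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal referrals in radiology reports: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radgraph)
```

## The problem

A radiology report usually states which prior exam the reader compared
against, most often by its date ("Vergleich mit CT vom 12.03.2015"), sometimes
by a literal expression ("heute", "gestern"), and sometimes by an explicit
statement that no prior exam exists. Extracting these *temporal referrals*
turns an archive of free-text reports into a directed graph of exams: nodes
are reports with their DICOM-style metadata (patient, modality, body region,
study date), and each referral becomes an edge from the referencing report to
the referenced one. On that graph, questions that are tedious against a flat
PACS list become queries: which studies belong to this disease course, which
follow-up skipped its comparison, which modalities refer to which.

radgraph implements the full chain — synthetic corpus generation, IOB2
sequence labeling, date normalization, link resolution with graded
confidence, graph construction/export, exploration queries and corpus
statistics — in base R, with igraph as the graph container.

## Annotation scheme

Five referral classes are used. `DATE`, `TODAY`, `YESTERDAY` and
`NO_PREVIOUS` are character-span annotations and may occur several times per
report; `MISSING` is a document-level, exclusive label for reports that
mention no comparison at all. A report's three-way *referencing status*
follows with precedence REFERENCED > NO_PREVIOUS > MISSING: any dated or
literal referral wins over a no-previous statement, which wins over silence.
The precedence matters for multi-organ reports that contain both a dated
comparison and a "no prior exam" sentence about another organ; ties are
resolved in favor of the stronger evidence of referencing.

All character offsets in the package are 0-based and half-open, and every
stage preserves span well-formedness (`surface == substr(text, start + 1,
end)`).

## The synthetic corpus

No clinical text ships with the package; a generator
(`generate_corpus()`) emulates the study conditions so that every stage is
testable end to end with exact ground truth:

* **Longitudinal histories.** Each patient receives `1 + Geometric(1/4)`
  exams (mean 4) with sorted random dates in 2011–2020; regions are drawn
  from two per-patient preferred regions to create realistic same-region
  follow-up chains.
* **Class mixture.** Referral classes are drawn per report as 44% `DATE`,
  27% `NO_PREVIOUS`, 23% `MISSING`, 6% `TODAY` — the annotation distribution
  the pipeline is meant to face. A first exam can carry no backward referral,
  so first exams renormalize onto `NO_PREVIOUS`/`MISSING`.
* **Resolvable ground truth.** Referenced dates are drawn from the patient's
  actual prior exams except for a configurable dangling fraction (default
  5%), so the correct link — including its confidence grade — is known by
  construction. `DATE` reports carry `Poisson(1.3)` extra referrals beyond
  the primary one.
* **Surface realism where it matters.** Reports are template-composed from
  the five customary sections (history, question, protocol, finding,
  impression). Dates render in mixed German formats (`12.03.2015`,
  `12.3.15`, `12.03.`, `12/03/2015`, `2015-03-12`), the year is omitted in
  8% of renderable cases, day-or-month-missing forms (`03/2019`) occur at
  2%, and the referenced modality is named in the same sentence with
  probability 0.7. A `p_noise` rate substitutes out-of-lexicon phrasings
  that the rule-based tagger cannot know.

What the generator does **not** emulate: spelling errors inside dates,
section-spanning referrals, negated or hypothetical comparisons, reporting
templates that vary by institution, and the long-tail phrasing variety of
real dictation. Perfect scores on noise-free synthetic text therefore
validate the *mechanics* (tokenization, tagging, arithmetic, linking), not
clinical-grade robustness; the measured tagger quality is a scaled-down
analogue of real-corpus performance, not a substitute for it.

With `p_noise = 0` the deterministic rule tagger recovers 100% of gold spans
by construction — that identity is itself a test, guarding the consistency
between generator and tagger conventions.

## The sequence tagger

The trainable tagger is a single-layer bidirectional LSTM over token
embeddings with a per-token softmax on the IOB2 label set (no CRF layer),
implemented natively in vectorized base R; gradients are checked against
finite differences in the test suite. `YESTERDAY` is excluded from the
trained label set by default (it is rare in practice) and handled by the
rule-based normalizer instead.

Choices a user may care about:

* **Embeddings.** Trainable, randomly initialized, 32-dimensional. Digits
  are normalized to a single shape (`12.03.2015` → `99.99.9999`) before
  vocabulary lookup, so unseen dates share the embedding of seen date
  shapes. No pretrained-vector download is required.
* **Hidden size 64 per direction, dropout 0.1** on the concatenated hidden
  state. These are the package's own defaults, chosen once for desk-scale
  training; capacity is generous for the template vocabulary.
* **Optimization.** Adam at learning rate `1e-2`, gradient-norm clip 5,
  batches of 1024 *tokens* (length-sorted, padded, masked). The batch unit
  is configurable; the token reading is the default because with randomly
  initialized embeddings, 1024-sentence batches leave so few optimizer
  updates per epoch that the patience-based early stop can fire while the
  entity-level validation F1 is still zero, collapsing training on some
  seeds. Token-counted batches keep the same per-batch budget while giving
  the protocol enough updates to converge.
* **Protocol.** 20% of reports (report-level) form the validation split;
  training runs at most 30 epochs with early stopping after 3 epochs of
  validation stagnation. The stopping metric is entity-level micro-F1 with
  validation loss as a lexicographic tie-break: in the first epochs a
  randomly initialized tagger predicts no entities at all, and without the
  tie-break "stagnation at F1 = 0" would end training before it begins.
  Weights are
  checkpointed per epoch (optional directory) and the best epoch's weights
  are the final model. `cross_validate()` assigns whole reports to folds
  (default 5). `grid_search_tagger()` loops a user grid over learning rates
  and batch sizes; the default grid contains the chosen operating point.

Evaluation (`ner_evaluate()`) is entity-level with exact span and class
match. Precision of an empty prediction set is reported as 0 rather than
NaN; zero gold support raises an error. Micro averages pool TP/FP/FN; macro
and weighted averages run over classes with nonzero support.

## Date normalization

`resolve_spans()` applies the rules in order: `TODAY` → the referencing
report's date; `YESTERDAY` → the day before; numeric dates parse day-first
(German convention). A date missing its year takes the referencing report's
year (`YEAR_IMPUTED`); a date missing day or month is discarded
(`DISCARDED_INCOMPLETE`); unparseable or impossible dates (`31.02.`) are
discarded (`DISCARDED_INVALID`).

Numerical details decided here because no convention was given:

* **Two-digit years** pivot into `[reference year − 99, reference year]`:
  "15" in a 2018 report means 2015, never 2115.
* **Future imputations.** The literal same-year rule can place `05.11.`
  (read in January 2018) in the report's future. The default keeps the
  literal rule; `strict_year = TRUE` decrements the year so resolved dates
  never postdate the referencing report. Links to future dates are dropped
  at the linking stage either way, so the graph's time invariant holds in
  both modes.
* **Day ranges** (`12.-14.03.2015`) resolve to the last complete date.

## Link resolution and confidence

For each resolved date, candidates are the same patient's exams on that
date (never the referencing report itself, never a later exam). Four
criteria are tried in order — (1) date + mentioned modality + body region,
(2) date + mentioned modality, (3) date + body region, (4) date — and the
first criterion with a candidate wins; 1 is the most confident grade, 4 the
least, and a referral with no exam on its date is discarded. The referenced
body region is taken to be the referencing report's region (region is not
extractable from a date sentence); the mentioned modality comes from a
German synonym lexicon (`modality_lexicon()`, user-extensible), with the
earliest match in the sentence winning and longer synonyms beating embedded
shorter ones ("PET-CT" is PT, not CT). When no modality is mentioned,
grades 1 and 2 are unsatisfiable by the letter of the criteria, and grading
starts at 3. Equal-grade ties break to the lexicographically lowest report
id — deterministic and seed-free. The test suite proves the grading
equivalent to an exhaustive best-match search over all candidate
configurations of two modalities × two regions.

## Graph, queries, statistics

The graph is a directed igraph multigraph; edges carry the reference class,
the extracted string and the confidence grade. Edges must point backward in
time; same-day edges are allowed (that is what `TODAY` produces) but
self-loops are not, so per-patient subgraphs stay acyclic. Exports:
GraphML, a lossless nodes/edges CSV pair, and a Cypher script with one
`CREATE` per node and edge for loading into a property-graph database.

`related_component()` returns the weakly connected component of a report —
by construction the same view from any seed node inside it.
`select_sequences()` matches linear patterns of step filters (modality,
region, keyword, date window) with per-pair gap bounds and optional
edge-connectivity, later exam as edge source. `detect_missing_links()`
flags same-patient pairs (earlier, later) within a gap window where the
later exam references neither the earlier exam **nor any exam on or after
its date**. The second clause is deliberate: in a chain A←B←C, exam C
references B and skips A, yet the comparison was superseded, not missed;
without the clause every transitively linked chain would be flagged. The
clause can be disabled (`require_superseded = FALSE`) for exhaustive
audits. Keyword filters are case-insensitive matches over the full report
text.

`status_summary()` reports counts and percentages (half-up rounding to one
decimal, so printed groups sum to 100.0 ± 0.1); `interval_summary()`
summarizes referral intervals in days per modality or region with
linear-interpolation quantiles (type 7), which is why even edge counts can
print half-day medians; empty groups yield no row rather than zeros.
Hypothesis tests on interval differences are out of scope.

## Problem sizes and determinism

The shipped tests train on corpora from ~40 up to ~2,800 reports (700
patients), the largest being the held-out quality check (2,000 training
reports, 220 test reports) — sizes chosen so the whole suite, including
one full training run, completes on a single CPU in minutes while leaving
the quality conclusion unchanged at larger n. Every stochastic step
(generation, splits, initialization, dropout, batch order) flows from
explicit integer seeds; the same seed and configuration reproduce a
byte-identical corpus and an identical training history on the same
platform.

## Known limitations

* Referral dates are not attributed to specific findings or measurements
  within the report; the link is report-to-report.
* Durations and fuzzy times ("vor 3 Monaten") are out of scope; only dated
  referrals and today/yesterday expressions are extracted.
* The German phrase and synonym banks are intentionally small and
  user-extensible; real deployments would grow them from local reporting
  customs.
* Synthetic fluency is not a goal: templates exercise the pipeline's
  failure modes (formats, partial dates, mentions, noise), not the
  linguistic variety of clinical German.
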