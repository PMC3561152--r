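---
title: "Identifying negated bio-events: models, features and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying negated bio-events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negev)
```

## The task

A *bio-event* is a structured semantic representation of a biological
action or relation: a trigger span in the text, an event type
(e.g. `positive_regulation`, `gene_expression`), role-labelled
participants (`theme`, `cause`) that may be entities or other events, and
optional attributes such as a location.  An event whose participants
include another event is *complex*.  A *negated* bio-event asserts the
non-existence of the event.  In the open bio-event corpora that annotate
polarity, roughly 6.1–6.4% of events are negated.

`negev` addresses the classification step only: gold event annotations are
assumed (read from BioNLP-ST-style standoff triples), and each event is
classified as `positive` or `negated`.  Event extraction, trigger
detection and entity recognition are out of scope.

Event-level negation is deliberately distinguished from negation-*scope*
detection.  A sentence can contain a cue and no negated event ("X
activates Y in the absence of Z"), a negated event and no cue (contrastive
constructions), or several events under one cue's scope of which only some
are negated.  The feature design below exists precisely because cue
presence alone is a poor classifier — the package ships that baseline
(`lexical_baseline()`) so the gap is measurable.

## Negation types

Five mechanisms of event negation drive both the feature design and the
synthetic generator templates:

1. **Inherent** — the trigger is itself a negative word
   ("Y is *unaffected* by X").
2. **Negated trigger** — an explicit cue modifies the trigger
   ("X does *not* activate Y").  The most frequent type by far.
3. **Negated participant** — the cue modifies a participant phrase
   ("X activates Y but *not* Z": only the Z-event is negated).
4. **Negated attribute** — the cue modifies a location phrase
   ("expressed in L1 but *not* in L2").
5. **Comparison/contrast** — negation is signalled by a contrastive
   construction with no explicit cue at all.

## Cue lexicons and deactivation

Four cue lists ship as plain-text data (`load_lexicon()`): `c40` (40
entries), `cBioScope` (28), `cBioInfer` (25) and `cCore`.  The printed
source of `cCore` states a size of 20 but lists 19 elements; the packaged
lexicon carries the 19 listed elements rather than silently "fixing" the
count.  Matching (`match_cues()`) is lemma-based and case-insensitive so
inflected instances (fails/failed) reach their citation form; multi-word
entries ("could not", "with the exception of") are matched longest-first,
left to right, and POS-restricted entries ("lack (noun)" vs "lack (verb)")
require a compatible tag.  `lose` and `lost` are kept as distinct `c40`
entries to stay faithful to the printed list.

A match on *not* is **deactivated** (flagged, never removed) when the next
token is one of *clear, evident, known, necessarily, only* — in corpus
analysis ~99% of events in sentences matching that pattern are positive.
No analogous pattern is applied to *no*: constructions like "no evidence
of", treated as non-negating in scope-annotation guidelines, demonstrably
do trigger negated events under event-level annotation, so the *no* cue
stays active.

## Parse layer

All features are computed from a per-sentence `parse_result()`: tokens
with lemma/POS, a dependency edge list, and a constituency tree.  The
parser is behind a backend contract; the shipped backend is a
deterministic fixture lookup, so the test suite and the generator need no
parser models.  Any tokenizer+tagger+parser stack that can fill the
container can be plugged in.

Decisions the literature leaves open, resolved here and isolated in one
operation each:

* **Command.** X C-commands Y (C ∈ {S, VP, NP}) iff neither dominates the
  other and X's lowest C-labelled ancestor dominates Y.  For distinct
  leaves the dominance clause is vacuous; a missing C ancestor yields
  `FALSE`, not an error.  The implementation is verified against a
  brute-force evaluation of the definition over all binary tree shapes up
  to 7 leaves.
* **Cue scope.** Computed as the contiguous range from the cue to the end
  of the smallest S-labelled constituent dominating it (whole sentence if
  none) — the dominant convention in the scope literature.  Alternatives
  can be swapped behind `cue_scope()`.
* **Dependency paths.** The dependency graph is treated as undirected;
  labels are reported in traversal order with `<`/`>` direction markers.
  Whether the original experiments used directed paths is unstated; the
  undirected choice is strictly more connective and is checked against an
  all-pairs shortest-path oracle.
* **Span heads.** The head of a multi-token span is the token whose
  governor lies outside the span, rightmost on ties — the standard
  head-percolation heuristic, deterministic by construction.

## Features

`extract_features()` emits a fixed 33-name schema (`FEATURE_SPEC`) per
event — syntactic (POS of trigger/theme/cause/cue heads), semantic (event
type, role set, participant-type set, complexity), lexical (cue presence
and identity, deactivator presence and relative position), lexico-semantic
(token distances cue↔trigger and cue↔location, cue-inside-trigger,
cue-precedes-trigger), dependency (existence/directness/first-label/length
of the chains cue↔trigger and cue↔location) and constituency (S/VP/NP
command cue→trigger and cue→location, scope membership of trigger,
participants and location).  Missing values always take declared sentinels
(`NONE`, `-1`, `FALSE`), never absent keys.

When a sentence holds several cues, the feature vector is computed against
the *nearest active* cue to the trigger head (leftmost on ties), and
deactivated matches contribute only the deactivator features — the source
experiments do not state their policy, so this one is documented and kept
in one function (`select_cue()`).  Surface distances are measured in
tokens between head tokens (characters would make the feature depend on
entity-name length).  POS features are retained although ablation
reportedly showed no gain: they are part of the described design and cost
nothing; feature-group ablations can drop them at the `vectorize()` stage.

Nested-event participants have no entity span; their trigger span stands
in for scope/POS purposes.  Attributes other than location (time,
experimental context) are ignored by the features.

`vectorize()` one-hot encodes categoricals with sorted names and sorted
levels, so the design matrix is bit-reproducible across runs and row
orders.

## Classifiers and evaluation

`polarity_model()` fits one of six algorithms, with hyperparameters
defaulting to the reference settings:

| algorithm | implementation | settings |
|---|---|---|
| `random_forest` | randomForest | 10 trees, `mtry = floor(log2(N+1))`, unlimited depth |
| `decision_tree` | rpart | ≥ 2 instances per leaf; cost-complexity pruning (`cp = 0.01`) as the analogue of C4.5's 0.25 pruning confidence |
| `logistic_regression` | `stats::glm` | — |
| `naive_bayes` | e1071 | Gaussian on the 0/1 design matrix; a small density floor at prediction replaces the "0.1 precision" convention |
| `svm_poly` | e1071 | polynomial kernel (degree 1 — the reference toolkit's default exponent), C = 1, attributes range-normalised |
| `nearest_neighbor_1` | class::knn1 | normalised Euclidean distance |

"`log(N+1)` features per tree" is read in the reference toolkit's base-2
convention.  The C4.5 discrepancy is deliberate: exact replication of a
specific toolkit's pruning is not attempted; a standard pruned CART
honouring the minimum-leaf constraint stands in, and the substitution is
confined to the `decision_tree` spec.

The positive class is `negated` throughout.  `prf()` computes
P = tp/(tp+fp), R = tp/(tp+fn), F = 2PR/(P+R) with 0/0 → 0;
`micro_average()` pools raw counts before computing metrics.
`cross_validate()` uses seeded, polarity-stratified folds (the original
fold construction is unstated; stratification with a recorded seed is this
package's choice), warns and degrades gracefully when a class has fewer
members than folds, and reports per-fold and pooled counts.
`run_cue_list_experiment()` re-featurizes once per lexicon under a fixed
model; `run_split_experiment()` partitions events three ways by type
(Class-1: localization, transcription, protein_catabolism,
gene_expression, phosphorylation; Class-2: binding; Class-3: the
regulation types) or two ways by complexity, scoring per class and
micro-averaging.

## The synthetic corpus

`generate_corpus()` is the test bed for everything above.  Its defaults
*are* the study conditions, fixed once:

* `negation_rate = 0.063` — the middle of the observed 6.1–6.4% range;
* `type_mix = (inherent 0.12, trigger 0.63, participant 0.11, attribute
  0.06, contrast 0.08)` — the micro-averaged type distribution;
* `complex_event_rate = 0.25` with a ×2.5 negation enrichment on complex
  events, matching the reported odds ratio (over 10% of complex vs 4% of
  simple events negated);
* distractor rates, chosen once as realistic rather than derived:
  5% of positive sentences use the deactivated "not only" pattern and 7%
  carry a cue over a fully positive event ("in the absence of"), so that
  cue presence alone over-predicts negation just as it does in real
  corpora.

Each template knows its own bracketing and dependency skeleton, so the
fixture parses are exact and deterministic; a closed vocabulary of protein
names, gene-expression nominals and cell types keeps the corpus free of
external resources.  Trigger-negation sentences draw their cue from the
configured lexicon's overlap with the supported forms (*not, cannot,
never, fail, could not*); contrast sentences carry gold negation with no
cue at all, deliberately stressing the classifier's ceiling.

What the generator does **not** emulate — and therefore what passing tests
do not show — includes real lexical diversity, discontinuous participant
spans, parse errors, cross-sentence structure, and ambiguous cue contexts
beyond the two distractor patterns.  Held-out scores on this corpus
measure that the feature scheme can recover the planted mechanisms, not
performance on GENIA-scale text; reproducing published corpus F-scores
requires the external corpora and is explicitly not attempted (the harness
accepts user-supplied standoff corpora in the same format).

## Numerical and degenerate-input conventions

* Character offsets are 0-based half-open everywhere in files; token
  indices are 1-based in the R API.
* Events straddling sentences are aligned to the trigger's sentence.
* `corpus_stats()` reports the negation percentage of an empty corpus as
  `NA`, never 0.
* A document that fails any invariant (span/text mismatch, dangling
  reference, cyclic nesting) refuses to read or serialize with an error
  naming the offending id; round-trip equality is structural
  (`doc_canonical()`), since record ids are regenerated on write.
* Fold sizes differ by at most one per class; every row is tested exactly
  once.

## Problem sizes

The end-to-end checks train on a 10,000-sentence default-condition corpus
(~12,800 events) with a stratified 50/50 split and evaluate the cue-free
ceiling on a 2,000-sentence contrast-only corpus; distributional checks
(binomial band for the planted rate, χ² for the type mix) run on the same
10,000-sentence corpus.  Unit and property tests use corpora of 100–1,500
sentences.

```{r example, eval = FALSE}
corp <- generate_corpus(generator_config(n_sentences = 1000, seed = 42))
rows <- featurize_corpus(corp, "c40")
v <- vectorize(rows)
cross_validate(v$x, v$y, model_spec("random_forest", seed = 42))
```

## Known limitations

* Contrast-type negations are invisible to the feature set (no cue, and
  the positive and negated co-events share identical features); recall on
  them is near zero by design, bounding overall recall at about 92% under
  the default mix.  Comparison/contrast marker features are a possible
  extension but are not specified anywhere and are out of scope.
* The `decision_tree` pruning is an analogue, not a replica, of C4.5.
* Discontinuous cues ("neither … nor") match as independent words.
* BioInfer- and GENIA-native XML dialects are not read; standoff is the
  canonical interchange.
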