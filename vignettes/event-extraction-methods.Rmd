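---
title: "Joint event extraction and the combination strategy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint event extraction and the combination strategy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bioevex)
```

## The task and the model

A biomedical event is a typed trigger word plus typed arguments whose
fillers are entity mentions or other events, so a sentence's events form
a directed acyclic graph. `bioevex` extracts such events from standoff
corpora with one shared encoder and three heads trained jointly, followed
by a penalty-minimising post-processor. This vignette records the model's
assumptions, the tunable parameters, and every place where the design was
genuinely open and a choice had to be made.

**Encoder.** Characters are embedded and convolved (kernel `char_kernel`,
`char_channels` output channels, leaky-relu) and max-pooled channel-wise,
so each word gets a fixed-length morphological vector regardless of
length; words shorter than the kernel are right-padded with a dedicated
PAD character, and pooling makes trailing pads inert. The
word/entity-label/character vectors are concatenated and encoded by a
bidirectional LSTM (`hidden` units per direction, `encoder_layers`
stacked layers, default 1). Gradients from all heads flow into this
encoder within one forward pass per sentence — parameter sharing is a
tested invariant, not an aspiration.

**Trigger recognition.** BILOU labelling, greedy left to right. The
feedback feature is the embedding of the *previously assigned* label
(learned start vector at position 1), which makes decoding sequential but
keeps it linear-time; no CRF or beam search, matching the greedy design.
The none-competitor of the support margin is the `O` class of the BILOU
inventory. Two open points were resolved as follows:

* the margin test is applied **per token**, and a decoded multi-token
  trigger's support is the **arithmetic mean** of its tokens' margins —
  scale-invariant in span length;
* argmax ties between non-none classes break to the lowest class index,
  making decoding deterministic.

Ill-formed label sequences are repaired, never rejected: an orphan `I`
opens a span, an orphan `L` acts as `U`, a type conflict inside a span
resolves to the opening token's type, and a span left open closes at its
last labelled token. Overlapping *gold* triggers (multi-label words)
keep the first mention in annotation order with a warning — the standard
single-label simplification.

**Relation classification.** Candidate pairs are ordered
trigger→(trigger|entity) pairs within one sentence; both orders of a
trigger–trigger pair are generated because nesting is directional, and
self-pairs are excluded. Segment slices are always taken in text order
with a binary direction flag appended to the feature vector; the token
distance `start2 − end1` is clipped to `[0, dist_clip]` (default 30) for
the embedding table, and adjacent or overlapping mentions use a learned
adjacency vector in place of the convolved between-segment. Predicted
roles that the schema forbids for the source trigger's type (with the
partner's category as filler) are post-filtered to none before event
evaluation.

**Event evaluation.** For each trigger, every subset of its emitted
relations that satisfies the schema's per-role min/max counts becomes a
candidate; enumeration is bounded (at most 14 relations per trigger enter
subset enumeration, and at most `candidate_cap` = 128 candidates survive,
both preferring the highest-support relations, with a warning when the
caps bite). A candidate is rendered as a role-label sequence: trigger
tokens carry `event_trigger`, each argument filler's tokens its role —
for a nested argument the *sub-event trigger's* tokens, since the
sub-event's own argument choice is resolved later by the selection step.
Overlap precedence is `event_trigger` > role > none, and between two
roles the earlier argument wins. Training labels: a candidate is positive
iff its argument set exactly matches a gold event's; per sentence,
negatives are undersampled to the positive count (one kept when no
positives exist). The modification head is trained on positive candidates
only, since gold modifications are defined only for real events.

**Selection (combination strategy).** With α, β, γ = 0.5, 0.25, 0.125,
the penalty charges `max(1 − α·s_e, 0)` per chosen event and
β·(positive trigger support) + γ·(positive relation support) per
*uncovered* trigger/relation. Waste terms clamp negative supports at
zero: an unconsumed trigger the model disbelieves should not reward
discarding events, which is what unclamped sums would do. The greedy
algorithm starts from the empty set and repeatedly adds the candidate
with the largest penalty decrease — O(|C|²) penalty evaluations — with
candidates considered in topological, children-first order of their
nested structure; a candidate whose nested filler trigger has no chosen
event yet is not addable, so a chosen child's support is in place before
its parent ("support transmission": the parent's relation to the child
trigger becomes coverable; the child's own s_e is never re-added to the
parent's term). One boundary case is worth stating precisely: a zero-gain
inclusion is admitted exactly when the candidate's own support-lacking
term vanishes (α·s_e ≥ 1) — a confidently valid event that costs nothing
is kept, which also makes the single-confident-candidate case behave as
expected; otherwise strict decrease is required, so ties favour smaller
event sets. Cyclic trigger-level nesting is broken before ordering by
dropping the lowest-support nesting edge (warning). The exact brute-force
minimiser (guard |C| ≤ 20, ties to smaller subsets then lexicographic
order) exists purely as a testing oracle; on 500 random instances the
greedy result is never better than the oracle and matches it in ≥ 99% of
cases. After selection a loop detector adds events one by one and drops
any that would close a cycle, and modifications are assigned by argmax of
p^(m) with ties resolved to None.

## Training

The four NLL terms (trigger, relation, validity, modification) are
summed unweighted; each is the class-weighted mean over a sentence's
items, averaged over the batch's sentences. Positive trigger/relation
classes carry weight `class_weight` = 5 against 1 for none, following the
5:1 positive:negative ratio. Optimiser: Adam at `lr` = 0.007 with L2
weight decay 2e-4, batch 16, Xavier initialisation, dropout (default 0.5)
on encoder LSTM outputs at training only. Trigger feedback uses scheduled
sampling, ε = k/(k + exp(epoch/k)) with k = 10. During training the
relation and event heads are teacher-forced on gold triggers and gold
relations (the trigger-label embeddings they consume come from the
scheduled-sampling-fed sequence); fully predicted pipelines run only at
prediction. Ensembles (`ensemble_size`, default 1; 5 is the
published-scale choice) train members from distinct derived seeds and
combine by **averaging per-class log-probabilities** before any
support/threshold logic — the combination rule was unspecified, and
averaging in log space keeps supports additive in member margins. The
greedy trigger pass feeds every member the embedding of the *combined*
decision, so members stay aligned and candidate sets need no union
bookkeeping.

Layer sizes (`word_dim` 32, `entity_dim` 8, `char_dim` 8, `char_channels`
16, `hidden` 32, head widths 64, EE hidden 32, label embeddings 8) are
package defaults, declared as configuration rather than claimed from any
external source.

## The synthetic generator

`generate_corpus()` produces seeded, schema-valid standoff corpora:
disjoint per-event-type trigger lexicons mixed with noise words (trigger
recognition is learnable but not from position alone), a fixed clause
order — non-first-role fillers before the trigger, first-role fillers
after — giving the relation classifier a positional and typed signal,
nested sub-events with probability `nesting_prob` (0.25), and
Negation/Speculation with probability `modification_prob` (0.1) cued by
"not"/"may" tokens. Documents have 1–2 sentences, sentences carry a
Poisson(1.2) number of top-level events (capped at 2) plus 0–2 extra
entity mentions. What it does **not** emulate: real biomedical syntax,
ambiguous or multi-label trigger words, discontinuous spans,
cross-sentence structure, and annotation noise. Passing tests on this
generator therefore demonstrate that the machinery — encoding, joint
training, enumeration, selection, serialisation, scoring — is correct and
learnable end to end; they say nothing quantitative about accuracy on
real corpora, which additionally require the external shared-task data
and long training runs.

The capacity check trains the default model (hidden 32) for 200 epochs on
a 20-document corpus (~30 sentences, ~35 events) — about 1.5 minutes on
one CPU — and requires training-set F1 ≥ 0.95; held-out documents from
the same generator typically score F1 ≈ 0.9–1.0. The loss-ordering
diagnostic summarises the training curves by (a) which head dominates the
early absolute loss decline (trigger recognition, which starts highest
and drops first) and (b) which head has the largest normalised
area-under-curve, i.e. changes slowest (event evaluation, whose signal
depends on the other heads' representations).

## Evaluation

Scoring uses approximate span matching — the predicted trigger must lie
within the gold span extended by one token on each side — and approximate
recursive matching — argument multisets must align role by role, entity
fillers by exact span and type, event fillers recursively under the same
relaxation. `strict = TRUE` switches both off. Matching is greedy 1–1 per
document; precision is 0 by convention when nothing is predicted. The
five error categories are assigned with the precedence wrong span →
wrong label → redundant arguments → wrong arguments → other, to each
unmatched prediction and each missed gold event not already accounted for
by a classified false positive on the same trigger — the precedence and
the denominator (gold + spurious events) had to be fixed here, as only
the category names are standard.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open everywhere (brat convention).
* The sentence splitter breaks on `[.?!]` + whitespace + capital/digit
  with a small abbreviation list; the tokenizer splits whitespace chunks
  and detaches leading/trailing punctuation, keeping internal hyphens and
  slashes. Both are deliberately simple, toolkit-free rules, pinned by
  fixtures.
* Empty sentences, empty candidate sets, documents without entities, and
  events without arguments are all legal inputs with defined outputs.
* All RNG consumption (initialisation, dropout, scheduled sampling,
  undersampling, generation) is derived from explicit seeds; fitting and
  prediction are bit-reproducible on CPU.
* Penalty comparisons use a 1e-12 absolute tolerance; supports and
  penalties are otherwise exact doubles.

## Known limitations

Single-sentence scope; one trigger label per token; no discontinuous
triggers or `*`-equivalence annotations; the exact minimiser is
deliberately unusable beyond |C| = 20; hand-written base-R networks are
CPU-bound and meant for corpora orders of magnitude smaller than
production shared-task training sets; pretrained embeddings are supported
only as random-initialisation replacements supplied by the user.
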