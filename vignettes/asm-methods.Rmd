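---
title: "Approximate subgraph matching for event extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate subgraph matching for event extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmevents)
```

## The model

A sentence is a labeled directed multigraph: tokens (with surface, lemma
and Penn POS tag) are nodes; collapsed-dependency relations are edges.
Parallel edges and cycles occur naturally in collapsed dependencies (a
relative clause can put both `nsubj(lead, ligation)` and
`rcmod(ligation, lead)` between the same token pair), so `dep_graph`
makes no simplicity assumption. Token indices are 1-based sentence
positions; collapsed-dependency copy tokens (`word-6'`) become distinct
tokens sharing the surface, preserving the injectivity semantics of
matching.

### Rule induction

Each annotated event contributes graph rules. On the undirected view of
the sentence graph, every shortest path from the trigger to each argument
is extracted (all of them when ties exist; multi-token triggers take one
shortest-path choice per trigger token, merged). Two rule families are
built:

* **union variants** — one rule per element of the Cartesian product
  across the arguments' path sets; the graph is the dependency path union
  of one choice per argument, depicting all participants jointly;
* **individual variants** — one rule per (argument, path), recovering
  arguments independently so that partial contexts still fire.

Annotated entity arguments are flagged as a generic `BIO_Entity` node:
their lexical features are masked during matching (original surfaces are
kept for reporting). Sub-event arguments anchor at the sub-event's
trigger token; the node keeps its lexical features in the stored rule but
is flagged so the matcher can relax it. The two-argument regulation
example with one theme path and two parallel cause paths therefore yields
2 union + 3 individual = 5 distinct rules. Rules are deduplicated
corpus-wide on (event type, canonical graph form, slot structure), with
node ranks replacing token positions and entity nodes interchangeable;
all provenances of a collapsed duplicate are retained because pruning
needs them for leave-origin-out evaluation. Degenerate zero-length paths
(trigger token = argument token) are kept only for events with no other
argument: single-node graphs carry no context.

### The subgraph distance

A rule graph matches a sentence graph through an injective node mapping
whose weighted distance is within the event type's threshold η
(inclusive — a closed interval, so η = 0 still admits exact matches):

* `struct_dist` — over all C(n,2) unordered rule-node pairs, the absolute
  difference between the rule-side and sentence-side undirected
  shortest-path lengths, summed and divided by the rule-side length sum.
  The normalization makes the component scale-free in rule size.
  A mapped pair disconnected in the sentence rejects the candidate
  (`Inf`).
* `label_dist` — per pair, the multiset symmetric difference between the
  edge labels on the rule path and on the selected sentence path
  (`prep_of` against `prep_in` counts two labels), totaled and divided by
  the summed path lengths of both sides; always in [0, 1].
* `directionality_dist` — identically, over forward/backward edge
  orientations relative to a traversal from the lower-token-index
  endpoint to the higher (in each graph independently).

Distances are asymmetric by design: the cost is that of transforming a
subgraph of the sentence into the rule, never the reverse.

Numerical choices where the procedure needed pinning down:

* When several sentence shortest paths connect a mapped pair, the one
  minimizing (label difference + orientation difference) is selected,
  ties broken by lexicographically smallest node sequence — the most
  favorable deterministic reading. On the rule side the reference path is
  the lexicographically smallest; rule graphs built from path unions
  rarely have ties.
* Matching enumerates candidate mappings from one fixed rule start node:
  the lowest-indexed `BIO_Entity` node if any (sentence candidates are
  then its entity tokens), else the lowest-indexed node (all sentence
  tokens are candidates). Fixing the start node does not reduce the
  solution set; the enumeration-equivalence property test covers this
  empirically.
* A guard (`scheme_cap`, default 100,000 schemes per start pair) bounds
  the documented exponential worst case; overflowing abandons the start
  pair with a warning rather than returning a truncated set.
* Zero total distance is equivalent to a distance-, label- and
  orientation-preserving embedding. This is slightly stricter than
  classical edge-preserving subgraph isomorphism when the sentence
  contains shortcuts between non-adjacent rule nodes; the oracle tests
  assert the distance-preserving reading.

### Node-match criteria

Non-entity nodes match under a conjunction of features: `P` exact POS,
`P*` relaxed POS class ({NN, NNS}, {NNP, NNPS}, the verb conjugations,
{JJ, JJR, JJS}, {RB, RBR, RBS}; others exact), `L` lemma, `A` exact
token, `T` membership of the sentence lemma in a trigger lexicon
collected from training triggers (the source of `T` is otherwise
undefined, so a lexicon is the package's choice). The default criteria
string is `"P*+L"`. A rule node without a lemma under `L` is a
configuration error; sentence tokens without lemmas simply never match,
so partially lemmatized corpora degrade gracefully instead of failing.

### Bottom-up extraction

Simple rules (no sub-event slot) are matched first. In later rounds,
complex rules are matched with the sub-event relaxation: a sub-event slot
node may map onto *any* token that triggers an already-extracted event,
ignoring that node's lexical features entirely — the contextual structure
linking sub-events generalizes across event types, so only "is a trigger
of an extracted event" is required (the stricter lexical reading remains
available by matching without the relaxation). Union-variant matches
yield complete events directly; arguments recovered by individual-variant
matches are grouped per (event type, trigger tokens) into one merged
event — multi-theme bindings merge rather than emitting pairwise events,
a deliberate reading of grouping-by-shared-trigger. Theme-less candidates
are discarded; exact duplicates collapse, with every contributing rule
retaining credit (attribution feeds pruning). Both the union and the
grouped-individual pathway are emitted and deduplicated; no precedence is
imposed between them. The candidate set grows monotonically within the
finite space of (type, trigger, argument) combinations, so the iteration
halts; a cap of 20 rounds is a safety net never reached on valid input.

### Rule-set optimization

Each rule's quality is its TP:FP ratio over training sentences, leaving
out the sentence(s) it was induced from; rules predicting nothing are
kept. Predicting rules below the ratio threshold (default 0.25, i.e. 1:4)
are removed, and the measure–rank–remove cycle repeats until an iteration
removes nothing — necessary because removing a sub-event-supplying rule
can starve a regulation rule of its true positives only in the *next*
pass. Two evaluation modes coexist deliberately: standalone `rule_stats`
substitutes **gold** sub-events for complex rules, isolating a rule's own
quality from other rules' errors, while the pruning iterations inside
`optimize_ruleset` use the **current rule set's** predictions, which is
what makes removals propagate through nested dependencies. Convergence
takes at most |ruleset| iterations since every non-final iteration
removes at least one rule.

### Parameter tuning

Thresholds (one per event type) and the three weights are integers in
[0, 50], searched by a seeded genetic algorithm maximizing the overall
strict F-score on development data (defaults: 50 generations × 100
individuals, mirroring the scale a full run would use). Selection,
crossover and mutation are unspecified in the method's source, so the
package documents its own choices: tournament selection (k = 2), uniform
crossover (p = 0.5), per-gene mutation (p = 0.1), elitism of 1. Ties
prefer the smallest thresholds, then the smallest weights — the most
conservative matcher at equal F. An exhaustive grid over thresholds is
available for small spaces and doubles as the oracle in tests.

## Default parameters

The shipped profile is the optimized setting for the GENIA event task
(dimensionless distance units; thresholds are on the same scale as the
weighted distance):

| parameter | value | | parameter | value |
|---|---|---|---|---|
| η Gene_expression | 7 | | η Regulation | 3 |
| η Transcription | 5 | | η Positive_regulation | 3 |
| η Protein_catabolism | 7 | | η Negative_regulation | 3 |
| η Phosphorylation | 10 | | w_s | 10 |
| η Localization | 10 | | w_l | 10 |
| η Binding | 7 | | w_d | 10 |

Unlisted event types fall back to `default_eta = 7` (the simple-event
level). Criteria `"P*+L"`, pruning ratio 0.25.

## The synthetic corpus generator

Real shared-task corpora are not redistributable, so every stage is
exercised on generated documents: random filler-token trees (plus a
bounded number of extra edges that create cycles and multiple shortest
paths, exercising the all-shortest-paths machinery), planted event
contexts in which a trigger token connects to each argument through a
labeled dependency chain, pre-annotated protein entities, nested
regulations, and — at a configurable rate — *distractor* contexts that
reuse rule lemmas in unannotated configurations, giving pruning genuine
false positives to remove. Text, offsets, `.a1`/`.a2` gold and both parse
dialects are emitted consistently; a fixed seed reproduces the corpus
byte-for-byte.

Argument paths in the default templates are two edges long, a choice made
from the distance algebra: with the default equal weights of 10, one
relabeled or flipped edge on a two-edge context costs a total distance of
5 — recoverable at η = 7 — while a single spliced node costs 9 and any
perturbation of a one-edge context costs 10. Raising η therefore recovers
perturbed contexts in a controlled order, which is the desk-scale
analogue of the approximate-vs-exact recall gain on real corpora: the
tolerance test perturbs 30% of edges (insertion/relabel/flip each) and
asserts that strict recall is non-decreasing in η and strictly higher at
η = 7 than at η = 0.

What passing these tests does *not* show: synthetic sentences have
vocabulary, length and ambiguity far below real biomedical text; parse
errors are emulated as independent uniform edge perturbations, not as the
systematic attachment errors real parsers make; and distractors are
graph-identical copies, a harsher precision test than natural
near-misses but a narrower one. Results on this corpus characterize the
algorithms, not expected performance on literature.

Problem sizes used by the shipped experiments: 20–50 documents of 2
sentences, ~12 tokens each, 200 random matching instances with rule
graphs up to 8 nodes and sentence graphs up to 25 nodes — comfortably
within the regime where the brute-force oracles stay exact.

## Known limitations

* Events crossing sentence boundaries are rejected on input; the
  extractor never proposes them.
* Speculation/negation attributes, equivalence (`*`) and modification
  (`M`) standoff lines, and site/secondary arguments are out of scope.
* The CoNLL writer serializes the first incoming edge per token (the
  format is tree-shaped), so multigraph sentences round-trip completely
  only through the Stanford-dependency triple dialect.
* The scorer's `approx_span` mode relaxes trigger spans by one token per
  side; it approximates, but is not identical to, the shared-task online
  scorer's approximate-span/approximate-recursive semantics.
* Lemmatization is an input: the package compares the lemmas it is
  given and ships no lemmatizer of its own.
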