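---
title: "Scoring drug-target interactions by multi-channel evidence fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-target interactions by multi-channel evidence fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtifuse)
```

## The problem

Whether a small molecule modulates a given protein is rarely settled by one
source of evidence. Structure-based machine-learning predictors generalize
from binding data but are opaque and can fail silently off-distribution;
curated interaction databases encode reliable but incomplete relational
knowledge; the literature holds dispersed textual evidence that no single
database captures. `dtifuse` scores a candidate drug-target pair on all
three axes independently, fuses the scores transparently, and keeps every
intermediate step inspectable - the setting is early-stage target
triage, where a false positive costs a wet-lab validation campaign and an
unexplained score is unusable for decision-making.

## The three evidence channels

### Knowledge-graph path score

The KG channel operates on an undirected graph whose nodes are drugs and
genes and whose edges are curated interactions (any conforming edge list
loads; the package does not ship a production graph). For a pair (d, t)
it enumerates every simple path of at most `max_hops` edges (default 4)
and weights each path by the connectivity of the nodes it traverses:

$$w(p) = \frac{1}{|p|} \sum_{i=1}^{|p|} \frac{\deg(n_i) + \deg(n_{i+1})}{2\,|V|}$$

i.e. the mean over the path's edges of the endpoint degrees normalized by
twice the node count. The pair score is 0 when either node is absent or
unreachable, exactly 1 for a direct edge, and otherwise

$$\max_{p \in P(d,t)} \;\mathrm{clamp}_{[0,1]}\!\left(\frac{w(p)}{\ln(1+|p|)}\right).$$

Two renderings of this scoring rule are typographically plausible -
multiplying or dividing by $\ln(1+|p|)$ - but only division makes the
score decrease with path length, which is the stated and biologically
sensible behaviour (a 4-hop association is weaker evidence than a 2-hop
one), so division is what the package implements. The direct-edge case is
pinned to exactly 1.0 rather than $w/\ln 2$: a curated direct interaction
is definitional evidence, not an inference, and the clamp guarantees the
open-path branch can never exceed it spuriously.

Degrees are counted on the deduplicated graph (distinct neighbors);
identifiers match case-insensitively after whitespace trimming, with no
synonym resolution - synonym mapping is a data-preparation concern with
no single right answer, so it stays upstream of the package. Ties between
equally scored paths break deterministically (fewer hops first, then
lexicographic node sequence), so evidence records are reproducible
byte-for-byte. Path enumeration is delegated to `igraph`; a configurable
cap (default 10,000 paths) bounds the evidence record on dense graphs,
flags the record as truncated, and makes the reported score a lower bound.

### Literature-search score

The search channel scores a set of $n$ results (title, link, content;
default $n = 10$) returned for the query `"<drug> <target> interaction"`.
Each result contributes three binary indicators: both names present; any
*positive* keyword present (`interacts`, `binds`, `activates`,
`modulates`); any *strong* keyword present (`strong`, `significant`,
`potent`, `effective`). With $T$ the indicator total and $M = 3n$ the
maximum, the channel score is $D = \mathrm{round}(T/M, 2)$, or 0 when
there are no results. Rounding is round-half-to-even (base R `round()`).

Matching is case-insensitive plain substring over title + content; links
are excluded because URLs rarely carry prose and would reward keyword-ish
slugs. Substring semantics are deliberately simple and documented: a
keyword inside a longer token still matches, and both keyword lists are
user-configurable arguments. Scoring is pure - the summary text, produced
separately by a text backend, can never change $D$.

The only search backend exercised anywhere in the package is a JSON
fixture (query string mapped to result records); a live web-search client
is representable but requires explicit opt-in and raises a typed error in
this build, keeping everything network-free.

### ML prediction

The ML channel is an adapter: any function from (names, SMILES, protein
sequence) to a score in [0, 1] can be plugged in, which is how a
pre-trained binding-affinity model is wrapped. The package treats backend
output as already probability-like and applies no recalibration. Two
offline backends ship: a lookup table (for precomputed model scores) and a
mock that hashes `(seed, drug, target)` onto [0, 1]. The mock is a pure
string-hash function rather than a draw from R's global RNG, so its scores
are stable across sessions and immune to other code touching
`.Random.seed` - determinism here is what makes the orchestrator's
byte-identical-CSV guarantee testable. The channel attaches the fixed
reason string "This agent used an ML model", since an adapter cannot
introspect an arbitrary wrapped model.

## Fusion and the reasoning trace

The final score is the unweighted arithmetic mean of the channels present,
rounded to five decimals. Optional per-channel weights (default 1, 1, 1)
are accepted for sensitivity analyses, but the mean is the standard rule:
with only three loosely calibrated channels there is no principled basis
for learned weights, and the mean makes ablation semantics exact - dropping
a channel is identical to averaging the remainder. The bundle validator
rejects empty bundles and any channel score outside [0, 1].

Each fusion emits a Thought - Action - Observation trace: an
`ANALYZE_EVIDENCE` step observing every channel score, an
`EVALUATE_MECHANISMS` step rendered only when the KG channel found a path
(it is the only mechanistic evidence available offline, e.g. "KG shows
3-hop connection via G1, D2."), and a `CALCULATE_SCORES` step whose
observation prints the exact arithmetic performed, not a description of
it. The free-prose reasoning field is rendered by a deterministic template
backend by default; a failing live text backend degrades to the template
with a warning and never affects scores.

## Format contracts and orchestration

Inter-stage payloads follow two strict contracts: channel outputs must be
`[drug, target, score]` and final records
`[drug, target, ai, kg, search, final, reasoning]`, with absent channel
scores rendered as the empty string. Wrong arity, wrong type, non-finite
values, or scores outside [0, 1] raise typed errors naming the offending
position - data-format drift between stages fails loudly rather than
propagating. The orchestrator replaces a conversational multi-agent
transport with direct function calls under the same contracts; the
contracts, not the chat mechanics, are the testable substance.

Batches are processed in chunks of `batch_size` (default 10 pairs at a
time). Under the default `skip` failure policy a failed channel drops out
of the mean with a warning and a failed pair becomes an error row, so the
output CSV always has one row per input pair.

```{r worked-example}
we  <- make_worked_example()
out <- run_pair(we$pair, we$config)
print(out$trace)
out$record$final_score
```

The worked example pins all three channel inputs: the lookup backend
serves the ML score, a planted fixture with indicator profile (9, 0, 0)
over 10 results realizes D = 0.3 (any profile with T = 9 would do - the
realization is arbitrary and documented), and the KG score is pinned
through an override hook because the production-scale graph that produced
it is not shipped. That hook is refused unless a configuration explicitly
enables it, so pinned scores cannot masquerade as computed evidence in
normal runs.

## Evaluation

`compute_metrics()` joins records to binary labels and reports F1,
precision, recall, specificity, AUROC and AUPRC. Scores at or above the
threshold (default 0.5, user-settable - no canonical binarization
threshold exists for fused scores) count as positive predictions. AUROC is
the Mann-Whitney rank statistic with midranks, so tied score pairs receive
half credit; AUPRC is step-wise integration of the precision-recall curve
with no interpolation (conventions differ between packages, so the choice
is stated). Conventions for degenerate cases: precision is 0 when nothing
is predicted positive; AUROC and specificity are `NA` when only one class
is present. A constant always-positive predictor therefore shows recall
1.0 and specificity 0.0 - the indiscriminate-prediction failure mode the
specificity metric exists to expose.

`repeated_subset_eval()` implements the repeated-subset protocol: seeded
sampling of `n_subsets` subsets of `subset_size` labeled pairs (defaults 5
and 50), reporting per-metric mean and SD.

## The fixture generators

The generators exist so every pipeline stage is testable offline with
ground truth known by construction, and they are first-class tested code.

* `make_graph()` plants relations exactly: a direct edge, or a
  node-disjoint chain of exactly k fresh intermediate nodes for `k_hop:k`
  (so k is provably the shortest path length), or nothing for `none`.
  Background drug-gene edges are sampled at `edge_density` only among
  non-planted nodes, so they can never create a shortcut through a planted
  chain. Default scale (6 drugs, 8 genes, density 0.15) keeps brute-force
  path enumeration instant while still producing multi-path graphs.
* `make_search_fixture()` inserts names and keywords into neutral filler
  text so each result's indicator triple is exactly the planted profile,
  making T and D known in advance. The filler vocabulary is chosen to
  contain no keyword substrings.
* `make_lookup_table()` and `make_labels()` complete the bundle;
  `simulate_fixtures()` writes all four artifacts as plain-text files.

All generators run under a local seeded RNG that restores the caller's
RNG state, so they are pure functions of their spec.

What the synthetic data does *not* emulate: real degree distributions of
biomedical knowledge graphs (hubs spanning orders of magnitude), genuine
literature prose (negations, hedging, co-mention without interaction), or
calibrated ML scores. Passing tests therefore demonstrate that the
arithmetic, contracts and determinism are correct, not that the fused
score is biologically well-calibrated on real data - calibration requires
a labeled benchmark and live backends, which are deliberately out of
scope here.

## Numerical and testing choices

Test problem sizes are chosen so exhaustive oracles stay trivially fast:
random graphs of at most ~25 nodes are compared against a from-scratch
recursive path enumerator plus independent recomputation of the weight
formula (200 seeded graphs), and AUROC is checked against the O(n^2)
concordant-pair count on 40 random score/label sets. Score equality in
those sweeps is asserted at standard floating-point tolerance; boundary
cases (direct edge 1.0, absent node 0) are asserted exactly because the
implementation pins them, not computes them.

## Known limitations

* The KG score is relation-agnostic and undirected; confidence-weighted
  or typed edges are not modeled.
* Substring keyword matching has no linguistic awareness; "X does not
  bind Y" scores as positive keyword evidence.
* The mean-fusion rule treats channels as exchangeable even though their
  calibration differs; weights are exposed but not learned.
* No synonym resolution: identifier mismatches silently score 0 on the KG
  channel (the evidence record's reason string does say why).
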