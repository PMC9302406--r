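---
title: "contactGO: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{contactGO: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactGO)
```

contactGO predicts Gene Ontology (GO) annotations for a query protein by
comparing its predicted residue–residue contact graph against a reference
collection and transferring terms from the most similar entries. This
vignette records the model, its assumptions, the parameters that matter,
the numerical conventions, and the choices we made where the design was
genuinely open.

## 1. From distograms to contact graphs

The input for a query is a *distogram*: for every residue pair, a
probability distribution over binned Cβ–Cβ distances (Cα for glycine).
The default binning is the common structure-predictor convention of
0.5 Å bins spanning 2–20 Å plus one open "no contact" bin beyond 20 Å.

A pair $(i, j)$ becomes an edge when

$$P(d_{ij} \le c) \;=\; \sum_{\text{bins with upper edge} \le c} p_{ij}(b)
\;\ge\; \tau,$$

with cutoff $c$ and probability threshold $\tau = 0.5$ by default. The
comparison is inclusive: a pair exactly at 0.5 is a contact. Because bin
masses are sums of floating-point values, the comparison carries a
$10^{-9}$ guard so that masses that should sum exactly to the threshold
are kept. The cutoff must coincide with a bin edge — anything else would
silently mis-state the probability being thresholded, so it is a
configuration error that names the two nearest valid edges.

**Parameters.**

* `cutoff` (Å): 8, 10 or 12 are the conventional choices; 12 Å is the
  default because the densest graphs discriminate folds best in this
  scheme, and because top-2 hit selection at 12 Å is the best-performing
  configuration of the method.
* `prob_threshold`: 0.5 (declare a contact when it is at least as likely
  as not).
* `min_separation`: 2 — residues $i, i\pm1$ are within any tested cutoff
  by covalent geometry and carry no fold information, so sequence-adjacent
  pairs are excluded by default. Whether such pairs were included in the
  original pipeline's graphs is not documented anywhere we could verify,
  so the setting is exposed rather than hard-coded.

Coordinates (PDB/mmCIF via bio3d) and CASP-RR contact lists are
alternative inputs; residues without a usable representative atom are
dropped from edge formation with a warning, and fewer than two resolvable
residues is a degenerate-input error.

## 2. Graph similarity

Two contact graphs are compared in two stages.

**Graphlet degree signatures.** Every node receives exact counts of the 15
automorphism orbits of the 9 connected graphlets on 2–4 nodes (orbit 0 is
the degree, orbit 14 a K4 position). Counting enumerates each connected
induced subgraph exactly once (ESU enumeration, implemented in C++) and
is validated in the tests against a naive subset-enumeration oracle.
Four-node graphlets are the standard compromise: 5-node orbits triple the
cost for little extra signal on graphs of a few hundred nodes.

**Signature similarity.** Orbits are weighted
$w_i = 1 - \log o_i / \log 73$, where $o_i$ counts the orbits that affect
orbit $i$ — i.e. the number of rooted orbit representatives that embed as
subgraphs of orbit $i$'s representative at its root, itself included. We
derived these counts by direct embedding enumeration:
$o = (1, 2, 2, 4, 3, 4, 3, 3, 6, 5, 8, 7, 11, 12, 15)$ for orbits
$0 \dots 14$. The per-orbit distance is log-scaled,
$d_i = |\log(u_i + 1) - \log(v_i + 1)| / \log(\max(u_i, v_i) + 2)$, and
node similarity is $1 - \sum_i w_i d_i / \sum_i w_i \in [0, 1]$.

**Alignment.** Because both graphs are proteins, their nodes carry a
sequence order; we align the two node orders globally by dynamic
programming (Needleman–Wunsch recurrence over the node-similarity matrix),
which yields the optimal *order-preserving* partial matching. Topology-only
(non-sequential) alignment is deliberately out of scope. The reported graph
similarity is the matched-pair similarity of the optimal alignment divided
by $\max(L_1, L_2)$, giving a score in $[0, 1]$ that is 1.0 exactly for
identical graphs. The gap contribution defaults to 0 (unmatched nodes add
nothing); ties in the recurrence resolve toward matching, then toward
consuming nodes of the first graph, so the mapping is deterministic.

This is a concrete, testable realization of graphlet-based contact-map
comparison; its scores satisfy the contractual properties (range,
self-similarity, symmetry, degradation under perturbation) but will not
numerically coincide with any particular external alignment binary, whose
internals differ in unpublished details. Downstream stages therefore treat
similarity scores as given inputs wherever published worked examples print
them.

## 3. Reference database and hit selection

Reference entries are contact graphs with precomputed signatures, filtered
to lengths 20–2000 inclusive ("shorter than 20" and "longer than 2000" are
excluded, so the bounds themselves are retained). Ortholog redundancy is
removed by the UniProt mnemonic convention: one entry per `CODE` prefix of
`CODE_SPECIES` names, keeping the lexicographically smallest full id — a
deterministic stand-in for an otherwise unspecified choice.

A search scores the query against every entry and ranks by descending
similarity, ties broken by ascending id. Three selection schemes are
provided:

* `score_threshold`: keep hits with similarity at least the parameter
  (0.5 being the classical notion of a "hit");
* `top_n`: keep the first N regardless of score (default, N = 2). Whether
  top-N should additionally enforce a 0.5 floor is ambiguous — "regardless
  of score" suggests not — so the default applies no floor and an optional
  `min_score` adds one;
* `z_score`: keep hits whose score is at least Z population standard
  deviations above the mean of the query's post-exclusion score
  distribution. A zero standard deviation makes the scheme undefined and
  is reported as an error suggesting another scheme.

Exclusion lists (the query itself, plus any externally determined
trivially identifiable references, e.g. by zero-E-value sequence hits) are
applied before selection; this package consumes such lists and never
computes E-values itself.

## 4. Annotation transfer and ensembling

For selected hits $k$ with similarity $s_k$, a term $i$ scores
$\sum_{k \,:\, i \in \mathrm{GO}(k)} s_k$, and scores are normalized by the
per-protein maximum so the top term scores exactly 1.0. Normalization is
global across the three GO namespaces (one maximum per protein), matching
the single-formula definition; a per-namespace variant can be had by
filtering annotations to one namespace before scoring. Whether hit
annotations should be propagated to ancestors before scoring is left as a
flag (`propagate_before_scoring`, default off: direct annotations), since
either convention is defensible.

The uniform baseline (`uniform_score_from_hits`) pools the union of the
top-10 hits' terms at score 1.0, the conventional scoring of plain
sequence-search baselines.

Ensembling averages normalized scores across methods with absent terms
counted as 0 — the only reading of "simply averaged" that is well-defined
when methods emit different term sets. The divisor is always the number of
methods, so a term predicted at 1.0 by every method stays at 1.0.

## 5. Ontology handling and evaluation

The OBO parser covers the 1.2/1.4 fields needed here; obsolete terms are
dropped (with a `replaced_by` map), `alt_id`s resolve to canonical ids,
and a cycle in the parent relation is a fatal error naming the cycle.
Propagation closes term sets over `is_a` and `part_of` only — the common
CAFA convention; `regulates` crosses semantic boundaries and is excluded.
Namespace roots are excluded from propagated sets as uninformative.

Information content uses base-2 logs and the reference annotation corpus
itself: $ic(t) = -\log_2(n_t / N)$ with $N$ the number of corpus proteins
carrying any term in $t$'s namespace, and the add-one guard
$-\log_2 (1/(N+1))$ for terms absent from the corpus. Smin is reported
unnormalized, in bits averaged per protein.

`fmax` scans thresholds 0.01–1.00 in 0.01 steps (the CAFA grid; finer
grids change nothing because predicted sets only change at observed score
values). Predicted sets are propagated at evaluation time; precision is
averaged over proteins with at least one predicted term (CAFA1
convention; `strict_precision` averages over all), recall over all
benchmark proteins. The smallest optimizing threshold is reported for
determinism. Proteins with empty truth are excluded with a warning. The
original evaluation protocol's exact conventions (propagation at
evaluation, precision denominator) are not fully documented, which is why
both are exposed as flags rather than guessed silently.

## 6. The synthetic benchmark

`generate_benchmark()` fabricates structural families: one random template
contact graph per family (lengths 40–60, edge density 0.1 over eligible
slots), two database members per family perturbed from the template by
independent 5% edge-slot flips, and one query per family at the spec's
perturbation rate (default 2%). Each family draws a leaf-biased set of 3
terms per namespace from a generated three-namespace `is_a` ontology
(single root and 20 terms per namespace, 3 levels); all proteins of a
family share those direct terms, plus occasional per-protein noise terms.
One global seed fans out to per-component streams, so every artifact is
bit-for-bit reproducible, and the ontology is emitted as deterministic
OBO bytes.

What this emulates: graded structural similarity within families against a
background of unrelated folds, and function that tracks structure — the
regime in which contact-graph retrieval is informative. What it does not
emulate: real fold statistics, predictor-specific distogram error modes,
disordered regions (where all predictions look alike and retrieval is
known to fail), multi-domain chimeras, or realistic GO term depth and
co-annotation structure. Passing the synthetic recovery tests therefore
demonstrates that the machinery is correct and that transfer works when
structure determines function; it does not measure accuracy on real
proteomes.

Problem sizes used by the tests: 30 families (60 database entries, 30
queries) for retrieval and transfer checks over 3 seeds; 100 random graphs
of up to 10 nodes for the orbit-count oracle; 50 random pairs of up to 6
nodes for the exhaustive alignment oracle; handcrafted 3-protein fixtures
for the exhaustive Fmax/Smin oracle. These sizes keep every oracle
brute-forceable while exercising all code paths.

## 7. Numerical conventions and degenerate inputs

* Distogram validation: per-pair bin sums within $10^{-4}$ of 1; bin-wise
  symmetry within $10^{-6}$.
* Thresholds are inclusive (`>=`) everywhere a published convention says
  "or larger"/"or higher": contact probability, hit score, Fmax/Smin
  threshold grid.
* Ranking ties: hit lists by ascending reference id; top-L/5 contact
  selection by descending confidence then ascending indices; evaluation
  reports the smallest optimizing threshold.
* Degenerate inputs error early and explicitly: empty databases, duplicate
  reference ids (listed), cutoffs off the bin grid (nearest edges named),
  fewer than two resolvable residues, L/5 < 1 for top-L/5 precision,
  zero score variance under Z-score selection.
* Per-query failures inside `run_pipeline()` skip that query with a
  warning and the run fails only if every query fails.

## 8. Known limitations

* Alignment is strictly sequence-order-preserving; circular permutations
  and domain swaps score poorly by construction.
* Scores are comparable within a database built at one cutoff, not across
  cutoffs.
* The OBO parser is minimal by design; exotic header-level constructs
  (term subsets, cross-namespace `intersection_of`) are ignored.
* The CLI config file is YAML; the parameter names mirror `run_config()`.
* Whole-proteome reference databases (hundreds of thousands of entries)
  are out of scope for the in-memory JSON archive; the format is intended
  for benchmark-scale collections.
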