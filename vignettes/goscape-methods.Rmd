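---
title: "Models and algorithms in goscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and algorithms in goscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goscape)
```

goscape works with Gene Ontology (GO) style graphs: terms connected by
child-to-parent "is a"-type edges into a rooted directed acyclic graph
(DAG), with gene annotations attached to terms. This vignette explains the
models and algorithms the package implements, the parameters that matter,
and the decisions taken where more than one reasonable design existed.

## The DAG, annotations and the true-path rule

An `ontology_dag` stores term ids, display names and the child-to-parent
edge set; the constructor enforces unique ids, known endpoints and
acyclicity. Annotation follows the *true-path rule*: a gene attached to a
term is implicitly attached to every ancestor. `propagate_annotations()`
materializes this by a single children-first topological pass in which each
term's gene set is the union of its direct genes and its children's
(already-final) sets. Because set union is associative and commutative the
result is independent of traversal order, and the operation is idempotent.
Two consequences are load-bearing elsewhere:

* the **superset invariant** — `genes(parent) ⊇ genes(child)` on every
  edge — which guarantees the buoyant layout exists (see below);
* the **node size** `|genes(term)|`, the quantity layouts and filters use.

OBO parsing is deliberately minimal: the tags `id`, `name`, `namespace`,
`is_a`, `relationship`, `is_obsolete` and `alt_id` of format version 1.2,
with a caller-supplied relation-type whitelist (only `is_a` for a
biological-process style ontology; all relationship types can be kept for a
cellular-component style one). Obsolete terms are recorded but carry no
relations; relations to unknown terms are dropped with a warning rather
than an error, because stray cross-references are common in hand-edited
files. gene2go parsing keeps all evidence codes by default and drops
NOT-qualified rows by default (`drop_not = FALSE` retains them) — the
conservative reading of qualifier semantics, made explicit as a flag
because curation practice varies.

## DAG refinement

For hypothesis testing, a parent annotated with exactly one of its
children's gene sets is pure redundancy: both terms yield identical test
statistics, so keeping the parent only inflates the multiple-testing
burden. `refine_dag()` removes such parents iteratively. Two details are
decisions rather than forced moves:

* **Schedule.** We remove one parent at a time, always the removable
  parent with the greatest root-bound depth, ties broken by term id, and
  re-examine the graph after every removal (removals can cascade: in a
  chain where all three terms carry the same gene set, removing the middle
  term makes the top term removable). The tested contract is the fixed
  point — the output contains no removable parent, and refining twice
  equals refining once — and any schedule reaching that fixed point would
  be acceptable; the deepest-first rule just makes the output
  deterministic.
* **Reconnection.** When a parent is removed, every one of its parents is
  connected to every one of its children. This preserves ancestry among
  the surviving terms exactly (the test suite checks the survivors'
  transitive closure against a brute-force closure of the input), at the
  cost of sometimes adding edges that transitivity already implies.
  `filter_by_size()`, which drops terms whose node size falls outside a
  user range, reuses the same reconnection rule for the same reason.

## Context and focus subDAGs

Anchors select subDAGs. A *root* anchor contributes its descendant
closure, a *leaf* anchor its ancestor closure, a *waypoint* anchor both;
multiple anchors combine by set union (the weakest assumption, since roles
are defined per anchor). The focus graph — the part drawn in full detail —
accepts waypoint or leaf anchors only and defaults to the context anchors
in leaf role. Two caps keep it small enough to draw: the anchor count
(`max_anchors`, default 10) and the descendant expansion (`expansion_cap`,
default 50): a waypoint anchor's full descendant closure is included only
when that closure has at most `expansion_cap` terms, otherwise only its
immediate children appear. Both defaults are package choices — tens of
nodes is where node-link displays stop being readable — and both are
plain arguments.

## The buoyant layout

Root-bound (longest distance from a root) and leaf-bound (longest distance
to a leaf, bottom-aligned) levelings are the standard Sugiyama options, but
on an ontology they mislead: the number of terms between a concept and the
root reflects how intensely an area has been curated, not how specific the
concept is. The buoyant layout replaces depth with annotation mass. It
requires:

1. **topological constraint** — every parent strictly above its children;
2. **descending node-size constraint** — a term with fewer annotated genes
   never above a term with more.

Under the superset invariant a parent's size is at least each child's, so
the two constraints are compatible and a valid leveling always exists.
`buoyant_levels()` computes one with the bubble-float algorithm:

* **Initialization.** Sort terms lexicographically by (node size
  descending, longest root distance ascending). The third key, term id
  ascending, is a package decision purely for determinism.
* **Float.** Walk the sorted order bottom-up, maintaining the current
  bottom-most open layer. The next term floats into the layer unless one
  of its strict descendants is already there, or the optional `max_span`
  cap (maximum size difference within one layer, absolute gene-count
  units, off by default) would be exceeded; on a conflict the layer closes
  and a new one starts above. Greedy maximal merging minimizes the level
  count subject to the scan order and is deterministic.

Levels are therefore contiguous blocks of the initialization order, both
constraints hold by construction, and the level count is at least the
root-bound layout's (which satisfies only the first constraint). The test
suite verifies all three properties on a thousand random DAGs and, on
small instances, checks the output against an exhaustive enumeration of
every constraint-valid contiguous-block partition. Equality with any
particular published rendering is *not* the contract — only
constraint-validity and the documented tie-breaks are.

## Within-level ordering and derived views

Horizontal order within levels is the classical crossing-minimization
problem, NP-hard already for two layers, so the package uses the standard
barycenter heuristic: four rounds of downward (parent-position) and upward
(child-position) sweeps, ties broken by term id. Anchors that share a
non-root common ancestor are grouped first, exclusive relatives (related
to exactly one group) join their group, and groups are kept contiguous on
every level by ordering on group-mean barycenters — the grouping reads
better even when it costs a few crossings. `count_crossings()` reports
crossings between consecutive levels so the heuristic's effect is
measurable.

The context silhouette is a per-level bar chart: total terms per level and
the subset that is ancestral or descendent to a highlight set (terms count
as their own ancestors and descendants). The binder order arranges terms
linearly by descending node size — with ties broken by buoyant level, then
id — and records where the buoyant level changes, so a renderer can
alternate background bands per level.

## Power analysis for enrichment testing

The simulator fixes the ground truth first: DE genes are a seeded uniform
sample of `ceiling(fraction * size)` genes from each chosen term
(`fraction = 1` takes the whole annotation). From the DE set,
`classify_nulls()` derives the non-null terms A1 under either framework:

* *self-contained*: non-null iff the term's genes intersect the DE set;
* *competitive*: non-null iff the DE fraction inside the term strictly
  exceeds the DE fraction of its complement ("at most as often" defines
  the null, so equality is null); terms annotated with the entire
  universe have no complement and leave the tested family.

Data are drawn from the simplest model that exercises the testing
pipeline: controls i.i.d. N(0, I), cases N(mu, I) with mu equal to
`beta_effect` at DE genes and 0 elsewhere. Because both groups share unit
variance, gene-level testing uses the pooled-variance two-sample t-test
(not Welch). An optional equicorrelation `rho` adds a shared per-sample
factor with unit marginals preserved, as a hook for correlated designs;
the default is 0.

Term-level p-values: Simes' rule `min_k m p_(k) / k` over a term's gene
p-values for self-contained tests; for competitive tests, genes are first
called significant — by default Bonferroni at 0.05/g, a deliberately
conservative and parameter-free cut, configurable to a fixed threshold or
any function — and the term's overlap with the significant set is tested
against the hypergeometric upper tail. Multiplicity is corrected across
all tested terms of the (refined, optionally size-filtered) DAG with
Benjamini-Hochberg at level q by default; Bonferroni and arbitrary plug-in
procedures are accepted. Refinement before testing matters: identical
parent/child gene sets would otherwise contribute duplicated p-values.

Per replication the simulator records the rejected set R and

Power = |A1 ∩ R| / max(|A1|, 1),  FDP = |R \\ A1| / max(|R|, 1);

the max guards define both as 0 when A1 or R is empty. Mean FDP across
replications estimates FDR. Seeding uses one master seed that draws a
table of per-(grid point, replication) substream seeds, so the whole grid
is reproducible and any single cell can be re-run independently.

Whether Simes p-values' dependence structure formally licenses BH across a
DAG of nested terms is not settled theory; the package reports empirical
FDP and makes no theoretical control claim. Empirically, at the scales the
tests run (a ~60-term, 600-gene synthetic DAG, one fully-DE mid-size term,
`beta_effect = 1`, 50 samples per group, 100 replications) mean FDP stays
below the nominal q = 0.1 and self-contained power is monotone over
n ∈ {5, 20, 80} at 50 replications each — those problem sizes are the
package's chosen trade-off between Monte-Carlo error and example runtime.

## The single-cell simulator

`simulate_sc()` emulates the confounding structure of cell-type signatures
in single-cell RNA-seq counts. Each signature type elevates its own genes:
counts are negative binomial with mean `signature_mean` (default 8) for a
gene in cells of its own type and `baseline_mean` (default 1) otherwise,
common size parameter `dispersion` (default 2), followed by independent
drop-outs: each entry is zeroed with probability `dropout_prob` (default
0.3), giving marginal mean `(1 - dropout_prob) * mu`. The default cell
counts (120, 150, 100 per signature type plus 300 baseline) mirror a
three-cell-cycle-state design. All rate parameters are package defaults
chosen to give clearly separated but overlapping count distributions at
realistic sparsity (roughly half of baseline entries zero); none is an
estimate from data. Drop-out is uniform — independent of gene mean and
cell — which is the main simplification relative to real data, where
drop-out probability falls with expression; a mean-dependent curve can be
layered on by post-processing, but the built-in model keeps the marginal
mean closed-form testable.

## The fixture generator

`random_godag()` draws DAGs with a fixed number of roots, each non-root
term taking 1..`max_parents` parents among earlier terms of a random
topological order, and leaf-weighted direct annotation (every leaf gets
1..`genes_per_leaf` genes; internal terms are directly annotated with
probability `direct_annotation_rate`). Leaf-weighting mimics GO curation
and produces the non-trivial size gradients that make refinement and the
buoyant layout worth testing. The generator reproduces exactly under its
seed. It makes no attempt at statistical realism of GO's degree
distribution; what passing tests on these fixtures establishes is the
correctness of the algorithms under the structural invariants
(rootedness, acyclicity, the superset invariant), not performance claims
on any specific GO release — figures computed on a pinned real release
(term counts, descendant counts, specific enriched-term lists) are
version-dependent and outside what synthetic fixtures can or should
reproduce.

## Degenerate inputs and numerical notes

* Zero pooled variance in a gene (possible only with degenerate inputs,
  not under the normal model) yields p = 1 with a warning.
* Empty p-value lists are an error for Simes; terms with empty
  annotations must be excluded from the tested family upstream, and
  `run_power_study()` errors if nothing is testable.
* An empty DAG refines and lays out to an empty result; a single term
  occupies level 0.
* All set operations are on character ids; term order in outputs is
  deterministic (topological or lexicographic as documented), so equal
  seeds give byte-identical exports.
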