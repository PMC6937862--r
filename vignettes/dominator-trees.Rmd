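---
title: "Dominator trees for positional analysis of mutated pathway genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominator trees for positional analysis of mutated pathway genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdom)
```

## The model and its assumptions

A signalling pathway is treated as a rooted digraph: nodes are protein
components (with protein complexes collapsed to single nodes), directed
edges follow the direction of signal flow, and the root is a user-chosen
entry point of the signal — a stimulus or a receptor.  Node `u` *dominates*
node `v` when every directed path from the root to `v` contains `u`; in
pathway terms, every signal reaching `v` must be relayed through `u`.
Domination is reflexive (by the standard convention adopted here: every
node dominates itself), transitive, and antisymmetric on distinct nodes, so
the strict dominators of any node form a chain.  The relation is captured
exactly by the unique *dominator tree*: the parent of `v` is its immediate
dominator `idom(v)` — the strict dominator closest to `v` — and tree
ancestry coincides with domination.

Two modelling assumptions matter in practice:

* **Edge semantics are uniform.** Activation and inhibition both become
  plain directed edges; the model asks whether a signal *can* reach a
  component, not what sign it carries.  Consequently "u dominates v" reads
  as "u gates all influence on v", whether stimulatory or inhibitory.
* **The root choice is part of the question.** Dominators are defined
  relative to the entry point; a different receptor yields a different
  tree.  Nodes with no *directed* path from the chosen root (for example a
  ligand feeding a different receptor) have undefined dominators; they are
  excluded from the tree and reported, rather than treated as an error.

The analytic payoff is positional: a mutated gene whose subtree is large
controls many downstream components — a candidate master regulator even at
low mutation frequency — whereas a mutated leaf cannot be responsible for
downstream deregulation (a passenger candidate).  Feedback loops make this
non-obvious: when a cycle can be entered from two branches, no cycle member
dominates another, and the nearest common controller may sit as far
upstream as the root.  `generate_fig1_fixture()` is the minimal example:

```{r fig1}
g <- generate_fig1_fixture()
dominator_tree(g)$idom[c("F", "H")]
```

## The algorithm and its verification

`dominator_tree()` implements the Lengauer–Tarjan semidominator algorithm
in the simple LINK/EVAL variant with path compression (`O(m log n)`), which
is exact — the "simple" refers only to the linking strategy's complexity
bound.  Verification is dual-route throughout the test suite: the same
`idom` map is reconstructed from the brute-force definition
(`dominates(u, v)` = `v` unreachable once `u` is deleted; `idom(v)` = the
strict dominator with the largest strict-dominator set), via
`idom_by_oracle()`, and the two must agree node-for-node on hundreds of
seeded random graphs; igraph's independent implementation is used as a
third opinion in one test.

Numerical/combinatorial choices:

* **Determinism.** Successors are iterated in lexicographic node-identifier
  order during the depth-first numbering, fixing every tie-break, so two
  runs on the same graph — or the same graph with permuted edge input —
  produce identical trees, and end-to-end CLI runs are byte-identical.
* **Self-loops and parallel edges** are dropped before the computation;
  neither can change domination.
* **Degenerate inputs.** A single-node graph yields an empty `idom` map and
  an empty edge set; unreachable nodes are excluded and listed.

## KGML handling

`parse_kgml()` captures KGML `entry` and `relation` elements.  Design
choices where the format leaves room:

* `map`-type entries (links to other pathways) and `maplink` relations are
  metadata only; the computable graph covers one loaded pathway.
* Compound entries (second messengers such as PIP3) are ordinary graph
  nodes: they relay signal even though they cannot be mutated.
* Groups (protein complexes) collapse to single nodes
  (`collapse_groups()`): edges re-attach to the group, duplicates merge,
  nesting flattens transitively; the operation is idempotent.  Complexes
  are drawn as boxes in DOT output.
* `binding/association` relations have no inherent direction and contribute
  edges both ways; every other subtype is directed source → target.  ECrel/
  PCrel relations keep their endpoint entries; no mediating node is
  inserted.  These orientation rules are documented package conventions,
  not properties asserted of any upstream tool.
* Display labels are the `graphics` name up to the first comma; the full
  comma-separated list supplies the node's gene symbols for mutation
  matching (case-insensitive exact HUGO-style symbols, no alias
  resolution — alias tables can be supplied as extra role-file rows).

## Mutation frequencies and colouring

The frequency of gene `g` is the number of distinct samples with at least
one qualifying record for `g`, divided by the number of distinct samples in
the *filtered* selection (types/datasets chosen by the user).  This
denominator choice keeps frequencies in [0, 1], makes them invariant to
duplicated rows and record order, and commutes with pre-filtering the
file; it is stated prominently because other tools count against a fixed
cohort size instead.  A node's frequency is the maximum over its member
genes — a complex is as mutated as its most mutated subunit — and its role
follows the precedence oncogene > tumour suppressor > neither, favouring
the activating interpretation for mixed complexes.

Categorical colouring: mutated nodes are red (oncogene), blue (tumour
suppressor) or grey (neither); unmutated nodes are uncoloured.  Gradient
mode bins frequency into `n_buckets` (default 5) equal-width buckets over
(0, max observed], with bucket 0 reserved for exactly zero; the bucket
count is configurable since any published gradient scale is a display
choice.

## What the synthetic data emulate — and what they do not

All test inputs are generated in code from fixed seeds:

* **Random rooted digraphs** (`generate_random_rooted_digraph()`):
  Erdős–Rényi edges plus a spanning arborescence, sizes up to 50 nodes and
  edge probabilities 0.02–0.22 in the tests — the density regime of KEGG
  signalling maps.  They exercise the algorithm, not biology.
* **The cascade fixture** (`generate_cascade_fixture()`): a ~40-node
  receptor → kinase cascade with side branches, one two-member complex and
  one deep feedback edge from a downstream kinase to an upstream adaptor
  substrate, as found in growth-factor signalling.  All symbols carry a
  `SYN` prefix; it is explicitly synthetic, not a KEGG pathway.
* **Mutation fixtures** (`generate_mutation_fixture()`): per-gene mutated
  sample sets of exact size `round(rate × n)`, recorded in a manifest, so
  expected frequencies are exact rather than statistical.  Test sample
  sizes (5–50) keep the arithmetic inspectable.

Passing tests therefore establish algorithmic correctness, format fidelity
and determinism.  They do not establish that real KGML files are always
well-formed (real exports have quirks the generator does not imitate), that
HUGO symbols in a real MAF match KEGG graphics names (aliasing is real and
unhandled by design), or anything about the biological validity of a chosen
root.

## Problem sizes and limitations

The validation suite compares the fast algorithm with the quadratic oracle
on 200 graphs of ≤ 50 nodes (the oracle, not the algorithm, is the
bottleneck: it performs one reachability sweep per node per graph);
all-pairs ancestry↔domination checks use ≤ 16-node graphs where the full
relation is enumerable.  The implementation itself is pure R and handles
KEGG-scale pathways (hundreds of nodes) instantly; it is not intended for
control-flow-graph workloads of millions of nodes.

Known limitations: inhibitory and stimulatory edges are indistinguishable;
dominators are recomputed from scratch after any graph edit (no incremental
maintenance); post-dominators are out of scope; and the mutation overlay
deliberately performs no statistical testing — it reports frequencies and
positions, leaving significance judgements to the user.
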