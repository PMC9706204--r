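---
title: "Detecting ancient allopolyploidy with MUL-tree reconciliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ancient allopolyploidy with MUL-tree reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulrec)
```

## The model

Whole-genome duplication by hybridization (allopolyploidy) leaves every gene
family with two homeologous copies, one per parental subgenome. Millions of
years later most families have lost one copy per descendant lineage, often
with a subgenome bias, so the surviving gene trees disagree both with each
other and with any singly-labelled species tree. `mulrec` formalises the
resulting inference problem:

* a **candidate reference** is either the singly-labelled species tree or a
  multi-labelled (MUL) tree built from a placement pair (H1, H2): the
  subtree of H1 is duplicated, the copy kept at H1's original position has
  its leaves tagged `*`, and a second copy tagged `+` is grafted onto the
  edge above H2 (a fresh node subdivides that edge). H2 = H1 grafts the copy
  as H1's sister - the autopolyploid form - and H2 = root attaches it as
  sister to everything;
* each rooted binary gene tree is embedded in each candidate by **LCA
  reconciliation** and scored by duplications + losses;
* the candidate with the lowest total score over all gene trees is the
  inferred history. A MUL candidate winning over the singly-labelled tree is
  evidence for polyploidy, and the winning (H1, H2) localises it.

The candidate space is enumerated exhaustively: H1 ranges over all non-root
nodes, H2 over H1 itself plus every node outside H1's subtree (root
included), with no topological deduplication - the space is a set of
*placements*, not of distinct shapes. On the package's 8-taxon reference
sampling (an outgroup, a 3-taxon "other"-lineage ladder, and a 4-taxon
"core"-lineage ladder) this yields 181 candidates.

### Counting conventions

Let `M(g)` be the LCA image of gene node `g` in the reference. `g` is a
duplication iff `M(g) = M(c)` for one of its children `c`. Each child edge
`(g, c)` contributes `depth(M(c)) - depth(M(g))` losses, minus one at
speciation nodes (the free edge crossed at the speciation itself). No losses
are charged above the gene-tree root, and none for the reference root edge:
only score *differences* between candidates matter for ranking, and these
conventions are the standard parsimony ones. Branch lengths and internal
labels are ignored throughout - scoring is purely topological.

### Subgenome assignment: groups and blocks

Against a MUL reference, a leaf of a duplicated species may map to the `*`
or the `+` copy. Two structures organise this choice:

* **polyploid groups** - maximal gene-tree subtrees whose leaves all belong
  to duplicated species. Their count is the complexity measure used by the
  preliminary filter (cap 8, i.e. at most 256 raw combinations), matching
  the upstream tool's semantics;
* **assignment blocks** - groups split top-down until each part contains at
  most one leaf per species. The exhaustive `2^blocks` search assigns each
  block to one subgenome copy.

The split matters. A family that retains both homeolog clades forms one
connected all-focal subtree; forcing that whole group onto a single
subgenome copy would charge a spurious duplication plus losses to exactly
the families that most strongly support allopolyploidy, and in simulation
the singly-labelled tree then outranks the generating MUL tree. A group with
several copies of one species cannot descend from one subgenome anyway, so
the block refinement is the coarsest unit that is biologically coherent.
Blocks refine groups and are refined by single leaves, so the block optimum
always lies between the group-forced score and the per-leaf brute-force
optimum; the test suite checks both inequalities, with equality whenever
every group is a singleton leaf.

Ties among equal-score assignments prefer more `*` blocks and then the
first assignment in enumeration order; ties among equal-score candidates
keep enumeration (preorder) order. Both rules exist only to make runs
bit-reproducible - the source protocol is silent on ties.

## Identifiability of H2 with a single outgroup

With one sampled outgroup and gene trees rooted by it, placements attaching
the second subgenome outside the focal clade (H2 at the root or on the
outgroup edge) cannot be distinguished from the placement joining the
subgenomes immediately basal to the focal clade (H2 = H1): after outgroup
rooting they all predict the same rooted gene-tree shapes, and the root-side
forms incur an extra spurious duplication against outgroup-rooted trees.
The simulator therefore uses H1 = the focal-clade ancestor with H2 = H1
(candidate id `H1=...|H2=SELF`) as its generating placement: it is the
representative of that equivalence class which the rooted data can actually
single out. Distinguishing true ancient allopolyploidy from autopolyploidy
at the same node requires either sampled parental lineages or copy
divergence information, both outside a topology-only analysis.

## Gene-tree filters

* *Preliminary filter*: drop trees with more than `group_cap = 8` polyploid
  groups.
* *Deep filter*: additionally require every species' copy number within
  bounds. The protocol this package follows states the bound inconsistently
  in two places ("more than one and less than four" vs "between one and
  five"); the default is the inclusive reading `[1, 4]` with presence
  required - the only reading compatible with single-copy families
  surviving to be classified - and `filter_config()` exposes
  `min_copies`/`max_copies` so either literal reading (`[2, 3]` or
  `[1, 5]`) can be selected.

Both filters are pure partitions: kept + rejected reproduce the input
exactly, and refiltering kept output changes nothing.

## Scenario classification

Classification restricts each gene tree to the focal species (outgroup and
other species only anchor rooting) and inspects the induced root's two
children. In **strict** mode - the default, mirroring literal pattern
matching on Newick strings - T1 requires one all-cladeA side and one binary
side with an all-cladeA and an all-cladeB child; T2 is the mirror image; T3
requires both sides binary with one all-A and one all-B child. **Lenient**
mode only requires "mixed" where strict requires the binary A|B structure,
accommodating multi-copy trees that can never match the literal pattern.
Classification keys on clade composition only, never on `*`/`+` tags: the
scenario formulas' tag decoration varies between sources and carries no
extra information once composition is fixed. Degenerate cases
(fewer than two focal leaves, multifurcating induced root) are labelled `U`
with a recorded reason.

## Enrichment

For each scenario, category over-representation is tested with the exact
hypergeometric upper tail `P[X >= k]`, computed from log-binomial
coefficients, and adjusted by the Benjamini-Hochberg step-up rule *within
each scenario* (the per-scenario panels this mirrors imply per-scenario
families of hypotheses). Both statistics are implemented from first
principles and are cross-checked in the tests against `stats::phyper` and
`stats::p.adjust` as independent oracles. The universe defaults to every
labelled family including `U` (annotations missing from a family keep it in
`N` but add it to no `K`); `universe = "classified"` restricts to T1/T2/T3.
No significance threshold is hard-coded - the table reports `p` and `q` and
leaves the cutoff to the analyst.

## The simulator

`sim_config()` defaults encode the package's standard study conditions:

| Parameter | Default | Meaning |
|-----------|---------|---------|
| `species_tree` | 8-taxon fixture | outgroup + 3-taxon cladeA + 4-taxon cladeB |
| `h1`, `h2` | focal ancestor, `"self"` | generating placement (see above) |
| `a` | 0.4 | P(lose the `+` copy across cladeB) |
| `b`, `c` | 0 | the other two clade-level loss indicators |
| `d` | 0.35 | P(lose the `*` copy across cladeA) |
| `eps` | 0.05 | per-leaf loss noise (outgroup exempt) |
| `delta` | 0 | per-branch small-scale duplication probability |
| `eta` | 0 | probability of one random NNI per tree |
| `n_families` | 500 | dataset size |

Loss acts at two levels because the scenarios are clade-level statements
while real gene trees are messier: the four Bernoulli indicators `a, b, c,
d` remove whole subgenome-by-clade blocks (producing the T1/T2/T3/U
structure, with closed-form fractions `T1 = a(1-d)`, `T2 = d(1-a)`,
`T3 = (1-a)(1-d)`, `U = ad` when `b = c = 0`), and leaf-level noise `eps`
then erodes individual genes. The truth label is computed directly from the
indicators - never by running the classifier - so classifier-recovery tests
are non-circular. Loss events are recorded as the number of maximal pruned
subtrees of the true MUL tree, which is the quantity LCA reconciliation can
observe (two sister leaves lost separately are one reconciliation loss).
Even so, reconciliation against the truth can undercut the recorded count
for reciprocal-loss (`U`) families - parsimony happily embeds `(B*, A+)` as
a single subgenome with one loss - so the invariant enforced in the tests
is `score <= losses applied`, with equality for T1/T2/T3 truths when
`eta = delta = 0`.

The outgroup leaf is exempt from `eps` and `delta`: it anchors rooting, and
a family that lost its outgroup would simply be unrootable and discarded
upstream. Families emptied of focal leaves are resampled and counted.
Gene-tree error is a single NNI move with probability `eta` - downstream
scoring is topology-only, so branch-length perturbation would be
unobservable. One seeded RNG stream drives every draw; identical
configurations give byte-identical datasets.

What the simulator does *not* model: incomplete lineage sorting (the
upstream analysis attributes conflict to hybridization + WGD; no coalescent
model is attempted), sequence-level error, alignment uncertainty, and
missing-data patterns correlated with assembly quality. Passing
parameter-recovery tests therefore show that the estimator inverts *this*
generative model, not that real datasets are free of those confounders.

## Numerical choices and problem sizes

* All counting is exact integer arithmetic; the only floating-point
  quantities are enrichment p-values (log-binomial sums, exact to machine
  precision at these sizes).
* The assignment search is exhaustive, never heuristic; the compiled kernel
  enumerates up to `2^30` masks in principle but the group cap keeps
  practical instances at or below `2^8`-`2^14`.
* Determinism: candidate order, block order, tie-breaks and the single RNG
  stream make every pipeline output byte-reproducible; `run_all()` reruns
  are compared verbatim in the tests.
* Test problem sizes were chosen as the smallest that exercise each claim
  with comfortable statistical margins: 1,000-tree Newick round-trips,
  200 random MUL instances and 1,000 singly-labelled instances for oracle
  equivalence, 500-family parameter recovery (the standard conditions),
  2,000 families for the closed-form fraction check (99% binomial CIs), and
  full enumeration of all hypergeometric draws up to `N = 12`.

## Limitations

* Topology-only: no branch lengths, no probabilistic duplication-loss
  model, no transfer events, no bootstrap-aware collapsing.
* Multifurcating gene trees are rejected rather than resolved by default;
  the reconciliation semantics assume binary gene trees.
* The H2 placement is only identifiable up to the rooted-data equivalence
  class discussed above; claims about *which* lineage contributed the
  second subgenome require sampling that lineage.
* Scenario counts from real data depend on the filters and the
  classification mode; strict and lenient modes bound the plausible range
  rather than pinpointing it.
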