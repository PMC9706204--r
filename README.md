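# mulrec

Inference of ancient allopolyploidy from gene-tree/species-tree reconciliation
with multi-labelled (MUL) trees, for phylogeneticists studying whole-genome
duplications (WGD) whose subgenomes have long since fractionated.

An allopolyploid lineage carries two subgenomes contributed by diverged
parental lineages. Long after the event, most gene families retain only one
homeolog per descendant lineage, so ordinary single-labelled species trees
explain the gene trees poorly and the WGD's nature (auto- vs allopolyploidy)
and placement stay ambiguous. `mulrec` addresses this by reconciling rooted
gene trees against *MUL trees*: species trees in which every species of a
putative polyploid clade appears twice, once per subgenome.

## The method

For a rooted binary species tree, the candidate space consists of the
singly-labelled tree itself plus one MUL tree per placement pair (H1, H2):
H1 is the polyploid clade (its subtree is duplicated; copies retained in
place are tagged `*`), and H2 is the attachment point of the second
subgenome's lineage (the duplicated copy, tagged `+`, is grafted onto the
edge above H2; H2 = H1 encodes autopolyploidy). For the 8-taxon sampling
used throughout (outgroup + a 3-taxon and a 4-taxon focal ladder) this gives
exactly **181 candidates**.

Each gene tree `G` is embedded in a candidate reference `S` by LCA
reconciliation: every node of `G` maps to the least common ancestor of its
children's images. A node is a **duplication** when its image equals a
child's image; **losses** accumulate per child edge as the number of skipped
reference edges (minus the one free edge at speciations). The
*reconciliation score* is duplications + losses; the candidate minimising
the total over all gene trees is the inferred history. Against a MUL
reference, leaves of duplicated species may descend from either subgenome:
maximal all-focal subtrees (polyploid groups) are split into
one-copy-per-species blocks, and all `2^blocks` subgenome assignments are
scored exhaustively (groups are capped at 8 per tree by the preliminary
filter).

Families are then classified by their homeolog retention pattern restricted
to the two focal lineages (cladeA = the "other" lineage, cladeB = the "core"
lineage):

| Label | Pattern at the induced root | Meaning |
|-------|-----------------------------|---------|
| T1 | `(A-only, (A, B))` | one subgenome copy lost in cladeB |
| T2 | `((A, B), B-only)` | one subgenome copy lost in cladeA |
| T3 | `((A, B), (A, B))` | both copies retained in both lineages |
| U  | anything else | unclassified (e.g. reciprocal loss) |

Per-scenario functional-category enrichment uses exact hypergeometric upper
tails with Benjamini-Hochberg adjustment within each scenario.

A seeded simulator generates gene families under this model (clade-level
subgenome-biased loss with probabilities `a, b, c, d`, per-leaf loss noise
`eps`, small-scale duplication `delta`, NNI topological error `eta`),
recording per-family ground truth for parameter-recovery experiments.

## Worked example

The `analysis/` directory holds the numbered workflow. Running

```sh
Rscript analysis/01_simulate.R 1   # seed 1
Rscript analysis/02_filter.R
Rscript analysis/03_candidates.R
Rscript analysis/04_reconcile.R
Rscript analysis/05_classify.R
Rscript analysis/06_enrich.R 1
Rscript analysis/07_subsampling.R 1
```

prints (seed 1):

```
simulated 500 families (seed 1, 0 resampled)
true placement: H1=a1,a2,a3,b1,b2,b3,b4|H2=SELF
T1=129 (25.8%)  T2=106 (21.2%)  T3=191 (38.2%)  U=74 (14.8%)
...
top 5 candidates by combined reconciliation score:
  1. H1=a1,a2,a3,b1,b2,b3,b4|H2=SELF        1031
  2. SINGLE                                 1717
...
T1=104 (24.0%)  T2=90 (20.7%)  T3=190 (43.8%)  U=50 (11.5%)
families with losses > duplications vs best candidate: 79.5%
agreement with simulator truth labels: 100.0%
...
  T1 top: C1 (k=67/104, K=107/434, p=1.54e-24, q=1.23e-23)
```

Reading: the generating MUL placement (the whole focal clade duplicated,
subgenomes joining at its ancestor) wins the 181-candidate search by a wide
margin over the singly-labelled tree (1031 vs 1717); strict scenario
classification recovers every simulated truth label; and the
scenario-enriched annotation categories surface at the top of their
scenario's table. The simulated scenario fractions track the closed-form
expectations `T1 = a(1-d) = 0.26`, `T2 = d(1-a) = 0.21`,
`T3 = (1-a)(1-d) = 0.39`, `U = ad = 0.14`.

## Package layout

- `R/` - tree I/O and containers (`parse_newick`, `rtree`), candidate
  enumeration (`enumerate_candidates`, `build_mul_tree`), reconciliation
  (`reconcile_single`, `reconcile_mul`, `score_all`, oracles), filters,
  scenario classification, enrichment, the simulator, and the `run_all()`
  orchestrator.
- `src/` - the compiled scoring kernel (LCA mapping and the assignment
  search).
- `analysis/` - the numbered workflow scripts shown above.
- `vignettes/mul-reconciliation.Rmd` - the methods vignette: model,
  conventions, design decisions and limitations.
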