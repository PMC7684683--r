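---
title: "Tree-linked assay experiments: model, conventions and design notes"
author: "treelink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-linked assay experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "##")
suppressPackageStartupMessages({
  library(treelink)
  library(SummarizedExperiment)
})
```

## The problem

Many assays produce a feature-by-sample matrix whose rows or columns carry a
hierarchy: OTU count tables come with a phylogeny or a taxonomy over the
features, and cytometry cluster profiles come with a dendrogram over the
clusters, while samples themselves may be grouped into a nested design. Two
practical problems follow. First, the matrix and the tree drift apart: rows
get filtered, trees get replaced or pruned, and the correspondence between a
matrix row and a tree node has to be re-derived by hand. Second, analyses are
often wanted at several resolutions at once -- per OTU, per genus, per
phylum -- which means repeatedly aggregating the matrix to sets of tree
nodes.

`treelink` addresses both with a container, `TreeExperiment`, that extends
`SummarizedExperiment` with an optional rooted tree per dimension and a
*link table* per tree that is maintained automatically by every operation.

## The container and its invariants

A `TreeExperiment` holds named assay matrices of one shape, row and column
annotation tables, optional row/column trees (`phylo` objects), link tables
(`rowLinks`, `colLinks`) and optional per-row reference sequences. The link
table has one row per assay row (column) and five columns: `nodeLab`,
`nodeLab_alias`, `nodeNum`, `isLeaf` and `whichTree`. Its invariants are
enforced by a validator after every operation: a link table is present
exactly when its tree is, its row count equals the dimension's length, and
`nodeLab`/`nodeNum`/`isLeaf` must cohere with the tree. Several rows may
link to one node -- in the worked example two entities map to the same leaf
-- and rows may link to internal nodes, which is how data already
aggregated at broader resolution is represented.

### Node numbering

All node addressing rests on one canonical numbering: tips are numbered
`1..n_tips` in their order of appearance (left to right in the Newick
string), internal nodes `n_tips+1` onward in preorder, so the root is
always `n_tips + 1`. Every parsed or edited tree is renumbered into this
form, so numbers are reproducible across write/parse cycles. Because
pruning renumbers nodes, the container's subsetting operator and
`subsetByNode()` deliberately do *not* prune trees; only `subsetByLeaf()`
prunes, and it carries node identity across the renumbering with alias
labels (`alias_{number}`, attached by `track_node()`).

### Label matching

Rows and columns are matched to trees by exact, case-sensitive label
equality, against real labels first and alias labels as a fallback (so rows
can be linked to unlabeled internal nodes). Entries that match nothing are
dropped from every aligned component with a single counting warning --
the tree determines what the container can describe. When *no* entry
matches, construction fails instead of returning an empty container; this
is a deliberate choice, since an all-dropped match almost always indicates
mismatched inputs rather than an intended empty result.

## Aggregation

For a target node set, each target's contributors are the rows (columns)
whose *linked node* lies in the target's descendant-or-self set. The
reducer (any vector-to-scalar function; `sum` and `mean` in the examples)
is applied per position of the opposing dimension. Consequences worth
stating explicitly:

* Targets may overlap; shared contributors enter each target
  independently. Aggregation therefore need not conserve totals unless
  the targets partition the linked leaves (with `sum`, partition targets
  conserve opposing-dimension totals exactly, which the tests assert).
* Contributors are defined over linked nodes, not only leaves, so a row
  linked to an internal node aggregates into that node's ancestors. A row
  linked to an ancestor *of* a target does not contribute to it; treating
  already-coarse rows as evidence for finer targets would double-count in
  partitioned analyses, so the descendant-or-self rule errs on the
  conservative side.
* Rows under no requested target are silently absent from the output
  (requesting a sub-hierarchy is routine); a target with *no*
  contributors yields a missing-value row and a warning, keeping the
  requested output shape.
* Output rows/columns are named by the targets' alias labels
  (`alias_{nodeNum}`), not their real labels, since internal nodes need
  not be labeled; links in the result point at the targets, so real
  labels are one `rowLinks()$nodeLab` away.
* With `rowBlock`, reduction is restricted within each value of a row
  annotation column (for example per-sample reduction of per-cell rows),
  producing one output row per (target, block) pair present among the
  contributors, named `alias_{nodeNum}.{block}`.

Annotation tables collapse per target (or per target-block group): a
column keeps a value only when all contributors agree on it, and becomes
missing otherwise. This is the strictest rule that never fabricates
metadata for an aggregate.

## Taxonomy tables as trees

`to_tree()` converts an ordered-rank table (broad to fine, one row per
entity) into a tree: leaves are the final-column values, internal nodes
are labeled `"{rank}:{value}"` so that the same name at different ranks
stays unambiguous, identical path prefixes merge, and branch lengths are
set to one (taxonomies have no meaningful lengths; unit lengths keep
distance functions total). A run of missing cells is bridged so a leaf
attaches to its deepest named ancestor. When several top-level values
exist, a synthetic root labeled `ALL` is added so the result is a single
rooted tree.

Conversion is only possible when no (non-missing) child value appears
under two parent values. `detect_loop()` reports all such polyphyletic
conflicts -- counting a missing parent as a parent value of its own --
and `resolve_loop()` repairs them by suffixing the child value `_{k}`,
numbering the distinct parents in first-appearance row order; the result
is loop-free and the repair is idempotent. Missing child values are
reported but not rewritten: they never become tree nodes, so suffixing
them would invent taxa. If a final-column value collides with an internal
label, validation fails rather than silently renaming a leaf.

## Numerical and format choices

* **Newick.** Serialization preserves stored child order (never sorts),
  writes branch lengths with 12 significant digits, and single-quotes
  labels containing reserved characters (the `:` in rank-prefixed labels,
  for instance), doubling embedded quotes. Parse errors report a
  character offset where one can be determined. Write-then-parse is
  lossless, including the numbering.
* **Pruning.** `keep_tips()` suppresses internal nodes left with a single
  child and sums their branch lengths (standard pruning semantics); a
  single retained tip yields the minimal two-node tree.
* **Distances.** `dist_node()` assumes unit branch lengths when a tree
  stores none, so it is total on taxonomy and cluster trees.
* **Bundles.** Containers serialize to a directory of delimited text
  (one TSV per assay, annotation and link tables, Newick trees, FASTA
  sequences) under a YAML manifest; `NA` is the missing marker and
  numbers carry full precision. Free-form `metadata()` is not serialized.
* **Ties and degenerates.** `join_node()` iterates sibling-set
  replacement to a fixed point, which preserves the descendant-leaf union
  exactly and is order-independent; zero-row subsets, empty node sets and
  fully labeled trees are all defined no-ops rather than errors.

## The built-in fixtures

`toy_fixture()` is a complete worked example chosen to exercise every
container feature at a glance: a 6 x 4 count matrix (a zero row atop the
values 1 to 20 filled by column, so every aggregate is checkable by
mental arithmetic), a four-rank taxonomy, two sample covariates (one
agreeing within sample groups, one not -- exercising both branches of
metadata collapse), a 5-leaf row tree with two rows sharing a leaf, and a
labeled column tree grouping the four samples pairwise.

`random_tree()` grows a binary tree by repeatedly splitting a uniformly
chosen tip and assigns uniform (0,1] branch lengths; `random_container()`
links rows to uniformly chosen nodes -- leaves and internals -- of a tree
about half the row count, so shared and internal links arise routinely.
These generators drive the property tests (node algebra against
brute-force edge-reachability oracles on trees of up to ~10 tips,
round-trip losslessness, link coherence after randomized operations) at
problem sizes of tens of rows, where exhaustive oracles are feasible and
the full suite runs in well under a minute. What the synthetic data does
not emulate: realistic abundance distributions, sparsity, compositional
structure, or deep unbalanced phylogenies. Passing tests therefore
demonstrate structural correctness of the bookkeeping and algebra, not
statistical behavior on real microbiome or cytometry data.

## Worked example

```{r example}
tse <- toy_fixture()
tse

rowLinks(tse)

# replace the phylogeny by the taxonomy and aggregate to phyla
taxa_tse <- changeTree(tse, rowTree = to_tree(as.data.frame(rowData(tse))),
                       rowNodeLab = rowData(tse)$OTU)
assay(aggregateByNode(taxa_tse, rowLevel = c("Phylum:B1", "Phylum:B2"),
                      rowFun = sum))

# subset to two leaves, pruning the row tree
subsetByLeaf(tse, c("t2", "t3"))
```

## Known limitations

One tree per dimension (the `whichTree` link column is the constant
`"phylo"`, kept for forward compatibility); no sparse or on-disk assay
backends; no unrooted trees; reducers are per-position scalar functions,
not matrix-level summaries; aggregation drops reference sequences, since
collapsing sequences across rows has no single defensible meaning; and
evaluation is serial -- at the intended problem sizes (up to a few
thousand rows) the bookkeeping, not the arithmetic, dominates.
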