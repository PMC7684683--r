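# treelink

Tree-linked assay experiments for R: a `SummarizedExperiment`-style
container for matrices whose rows and/or columns are tied to the nodes of
rooted trees, plus the node algebra and taxonomy tooling that goes with it.

## The problem

Microbiome count tables come with a phylogeny or taxonomy over their
features; cytometry cluster profiles come with a cluster dendrogram;
sample sets often carry a nested grouping. Keeping the matrix and the
hierarchy consistent through filtering, tree replacement and pruning is
error-prone, and analyses are routinely wanted at several resolutions of
the hierarchy at once.

`treelink` stores assays, annotation tables, row/column trees and
automatically maintained **link tables** in one object, `TreeExperiment`.
Each link-table row ties an assay row (or column) to a tree node:

| nodeLab | nodeLab_alias | nodeNum | isLeaf | whichTree |
|---------|---------------|---------|--------|-----------|
| t3      | alias_1       | 1       | TRUE   | phylo     |

Nodes are addressed by a canonical numbering (tips `1..n` in order of
appearance, internal nodes in preorder, root `n+1`) or by labels; every
node also carries a synthetic alias label `alias_{number}` so its identity
survives pruning and renumbering.

The core operation is node-level aggregation. For a target node set
`V`, each `v in V` becomes one output row (column) with entries

    y[v, j] = f({ x[i, j] : link(i) in descendants(v) ∪ {v} })

for a reducer `f` (sum, mean, median, ...). Targets may overlap, rows may
link to internal nodes, and annotation tables collapse to the value shared
by all contributors (else `NA`). A `rowBlock` column restricts reduction
within blocks (e.g. per-sample summaries of per-cell rows). Ordered-rank
taxonomy tables convert to trees with `to_tree()`, after polyphyletic
conflicts are reported by `detect_loop()` and repaired by
`resolve_loop()` (`Ruminococcus` under two families becomes
`Ruminococcus_1`, `Ruminococcus_2`).

## Worked example

```r
library(treelink)
library(SummarizedExperiment)

tse <- toy_fixture()          # 6 entities x 4 samples, two trees
rowLinks(tse)[1:3, ]
## LinkFrame with 3 rows and 5 columns
##             nodeLab nodeLab_alias   nodeNum    isLeaf   whichTree
## entity1          t3       alias_1         1      TRUE       phylo
## entity2          t3       alias_1         1      TRUE       phylo
## entity3          t2       alias_2         2      TRUE       phylo

# swap the phylogeny for the taxonomy and sum OTUs into phyla
taxa_tse <- changeTree(tse, rowTree = to_tree(as.data.frame(rowData(tse))),
                       rowNodeLab = rowData(tse)$OTU)
assay(aggregateByNode(taxa_tse, rowLevel = c("Phylum:B1", "Phylum:B2"),
                      rowFun = sum))
##          sample1 sample2 sample3 sample4
## alias_8        1       6      11      16
## alias_10      14      34      54      74
```

The two output rows are the phylum nodes (numbers 8 and 10 of the
taxonomy tree, hence the alias names); each entry is the sum of the
counts of the OTUs below that phylum in that sample. Aggregating the
sample dimension instead (`colLevel = c("GroupA", "GroupB")`, `colFun =
sum`) gives per-group totals and collapses the sample covariates to the
values shared within each group. Subsetting never prunes trees
(`x[i, j]`, `subsetByNode()`), except for `subsetByLeaf()`, which prunes
the row tree and remaps links through alias tracking:

```r
subsetByLeaf(tse, c("t2", "t3"))
## class: TreeExperiment
## dim: 3 4
## ...
## rowLinks: a LinkFrame (3 rows)
## rowTree: 1 phylo tree(s) (2 leaves)
```

A standalone node-algebra toolkit operates on any `phylo` tree:
`find_descendant()`, `find_ancestor()`, `share_node()` (lowest common
ancestor), `union_leaf()`, `join_node()` (minimal ancestor
representation), `dist_node()`, `mat_tree()`, `keep_tips()`,
`as_leaf()`, `track_node()`, `add_label()`, and friends. Containers
serialize to plain-text directory bundles (TSV + Newick + FASTA + YAML
manifest) via `write_bundle()`/`read_bundle()`, and a CLI wraps the
common workflows:

```sh
inst/scripts/treelink fixture toy -o demo
inst/scripts/treelink aggregate demo --row-level 7 8 --row-fun sum
inst/scripts/treelink tree convert --tree demo/col_tree.nwk GroupA GroupB
# 6 7
```

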