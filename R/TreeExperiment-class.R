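#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay
#'   rowData colData assayNames
NULL

#' Link table between assay dimensions and tree nodes
#'
#' A `DataFrame` subclass with one row per linked assay row (or column)
#' and exactly the columns `nodeLab` (the node's label, falling back to
#' the alias when the node is unlabeled), `nodeLab_alias`
#' (`"alias_{nodeNum}"`), `nodeNum`, `isLeaf` and `whichTree` (constant
#' `"phylo"`: one tree per dimension).
#'
#' @aliases LinkFrame-class
#' @export
setClass("LinkFrame", contains = "DFrame")

.link_cols <- c("nodeLab", "nodeLab_alias", "nodeNum", "isLeaf", "whichTree")

setValidity("LinkFrame", function(object) {
  if (!identical(colnames(object), .link_cols))
    return(paste("a LinkFrame must have columns",
                 paste(.link_cols, collapse = ", ")))
  TRUE
})

# links for a vector of resolved node numbers
.tl_links <- function(tree, num, row_names = NULL) {
  num <- unname(num)
  df <- S4Vectors::DataFrame(
    nodeLab = .tl_label_or_alias(tree, num),
    nodeLab_alias = .tl_alias(num),
    nodeNum = as.integer(num),
    isLeaf = num <= .tl_ntip(tree),
    whichTree = rep("phylo", length(num)))
  rownames(df) <- row_names
  methods::new("LinkFrame", df)
}

#' TreeExperiment: assay data linked to row and column trees
#'
#' `TreeExperiment` extends [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with an optional rooted tree on each dimension (`rowTree`, `colTree`),
#' automatically maintained link tables (`rowLinks`, `colLinks`) tying
#' each assay row/column to a tree node, and optional per-row reference
#' sequences. Several rows (or columns) may link to the same node.
#'
#' @slot rowTree,colTree A `phylo` tree or `NULL`.
#' @slot rowLinks,colLinks A [LinkFrame] or `NULL`; present exactly when
#'   the matching tree is present, with one row per assay row/column.
#' @slot referenceSeq An `XStringSet` (or `NULL`) with one sequence per
#'   assay row.
#'
#' @aliases TreeExperiment-class
#' @export
setClass("TreeExperiment",
  contains = "SummarizedExperiment",
  slots = c(rowTree = "ANY", colTree = "ANY",
            rowLinks = "ANY", colLinks = "ANY",
            referenceSeq = "ANY"),
  prototype = methods::prototype(rowTree = NULL, colTree = NULL,
                                 rowLinks = NULL, colLinks = NULL,
                                 referenceSeq = NULL))

.check_dim_links <- function(tree, links, len, what) {
  if (is.null(tree) != is.null(links))
    return(sprintf("%sTree and %sLinks must be present together", what, what))
  if (is.null(tree))
    return(NULL)
  if (!inherits(tree, "phylo"))
    return(sprintf("%sTree must be a phylo tree", what))
  if (!methods::is(links, "LinkFrame"))
    return(sprintf("%sLinks must be a LinkFrame", what))
  if (nrow(links) != len)
    return(sprintf("%sLinks has %d rows for %d %ss", what, nrow(links),
                   len, if (what == "row") "row" else "column"))
  num <- links$nodeNum
  if (any(num < 1L | num > .tl_nnode(tree)))
    return(sprintf("%sLinks nodeNum outside the tree", what))
  if (!identical(links$isLeaf, num <= .tl_ntip(tree)))
    return(sprintf("%sLinks isLeaf inconsistent with the tree", what))
  if (!identical(links$nodeLab_alias, .tl_alias(num)))
    return(sprintf("%sLinks alias labels inconsistent", what))
  if (!identical(links$nodeLab, .tl_label_or_alias(tree, num)))
    return(sprintf("%sLinks nodeLab inconsistent with the tree", what))
  NULL
}

setValidity("TreeExperiment", function(object) {
  msg <- c(
    .check_dim_links(object@rowTree, object@rowLinks, nrow(object), "row"),
    .check_dim_links(object@colTree, object@colLinks, ncol(object), "col"))
  rs <- object@referenceSeq
  if (!is.null(rs) && length(rs) != nrow(object))
    msg <- c(msg, sprintf("referenceSeq has %d sequences for %d rows",
                          length(rs), nrow(object)))
  if (length(msg)) msg else TRUE
})

#' Construct a TreeExperiment
#'
#' Assembles assay matrices, annotation tables and optional row/column
#' trees into a linked container. Rows (columns) are matched to tree
#' nodes by label: the explicit `rowNodeLab` (`colNodeLab`) vector when
#' given, otherwise the dimension names. Tree data takes precedence:
#' rows/columns whose label matches no node label (nor alias label) of
#' the tree are removed from every aligned component, with a single
#' warning reporting the count.
#'
#' @param assays A matrix or named list of same-shaped matrices.
#' @param rowData,colData Optional annotation tables aligned to the
#'   dimensions.
#' @param rowTree,colTree Optional `phylo` trees.
#' @param rowNodeLab,colNodeLab Optional character vectors (one entry per
#'   row/column) of node labels used for matching instead of the
#'   dimension names.
#' @param referenceSeq Optional `XStringSet` (or character vector), one
#'   sequence per row.
#' @param metadata A free-form list.
#'
#' @return A [TreeExperiment-class] object.
#'
#' @examples
#' tse <- toy_fixture()
#' rowLinks(tse)
#'
#' @export
TreeExperiment <- function(assays, rowData = NULL, colData = NULL,
                           rowTree = NULL, colTree = NULL,
                           rowNodeLab = NULL, colNodeLab = NULL,
                           referenceSeq = NULL, metadata = list()) {
  if (is.matrix(assays))
    assays <- list(assays)
  args <- list(assays = assays, metadata = metadata)
  if (!is.null(rowData)) args$rowData <- rowData
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  if (!is.null(referenceSeq) && is.character(referenceSeq))
    referenceSeq <- Biostrings::BStringSet(referenceSeq)
  if (!is.null(referenceSeq) && length(referenceSeq) != nrow(se))
    .tl_stop_val("referenceSeq must have one sequence per row (",
                 length(referenceSeq), " vs ", nrow(se), ")")
  x <- methods::new("TreeExperiment", se, referenceSeq = referenceSeq)
  if (!is.null(rowTree) || !is.null(colTree))
    x <- changeTree(x, rowTree = rowTree, rowNodeLab = rowNodeLab,
                    colTree = colTree, colNodeLab = colNodeLab)
  x
}

# ---- accessors --------------------------------------------------------

#' Accessors for trees, links and reference sequences
#'
#' `rowTree()`/`colTree()` get or set the dimension trees (setting `NULL`
#' clears the tree and its links; setting a tree re-links, see
#' [setRowTree()]). `rowLinks()`/`colLinks()` return the link tables
#' (`NULL` when the tree is absent). `referenceSeq()` gets or sets the
#' per-row sequences.
#'
#' @param x A [TreeExperiment-class].
#' @param value Replacement value.
#' @return The accessed component, or the modified object for setters.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rowTree", function(x) standardGeneric("rowTree"))
#' @rdname accessors
#' @export
setGeneric("colTree", function(x) standardGeneric("colTree"))
#' @rdname accessors
#' @export
setGeneric("rowLinks", function(x) standardGeneric("rowLinks"))
#' @rdname accessors
#' @export
setGeneric("colLinks", function(x) standardGeneric("colLinks"))
#' @rdname accessors
#' @export
setGeneric("rowTree<-", function(x, value) standardGeneric("rowTree<-"))
#' @rdname accessors
#' @export
setGeneric("colTree<-", function(x, value) standardGeneric("colTree<-"))
#' @rdname accessors
#' @export
setGeneric("referenceSeq", function(x) standardGeneric("referenceSeq"))
#' @rdname accessors
#' @export
setGeneric("referenceSeq<-", function(x, value)
  standardGeneric("referenceSeq<-"))

#' @rdname accessors
setMethod("rowTree", "TreeExperiment", function(x) x@rowTree)
#' @rdname accessors
setMethod("colTree", "TreeExperiment", function(x) x@colTree)
#' @rdname accessors
setMethod("rowLinks", "TreeExperiment", function(x) x@rowLinks)
#' @rdname accessors
setMethod("colLinks", "TreeExperiment", function(x) x@colLinks)

#' @rdname accessors
setReplaceMethod("rowTree", "TreeExperiment", function(x, value)
  setRowTree(x, value))
#' @rdname accessors
setReplaceMethod("colTree", "TreeExperiment", function(x, value)
  setColTree(x, value))

#' @rdname accessors
setMethod("referenceSeq", "TreeExperiment", function(x) x@referenceSeq)

#' @rdname accessors
setReplaceMethod("referenceSeq", "TreeExperiment", function(x, value) {
  if (!is.null(value) && is.character(value))
    value <- Biostrings::BStringSet(value)
  if (!is.null(value) && length(value) != nrow(x))
    .tl_stop_val("referenceSeq must have one sequence per row (",
                 length(value), " vs ", nrow(x), ")")
  x@referenceSeq <- value
  methods::validObject(x)
  x
})

# ---- display ----------------------------------------------------------

.tl_tree_line <- function(name, tree) {
  if (is.null(tree))
    sprintf("%s: NULL", name)
  else
    sprintf("%s: 1 phylo tree(s) (%d leaves)", name, .tl_ntip(tree))
}

.tl_links_line <- function(name, links) {
  if (is.null(links))
    sprintf("%s: NULL", name)
  else
    sprintf("%s: a LinkFrame (%d rows)", name, nrow(links))
}

#' @export
#' @describeIn TreeExperiment Compact display: the SummarizedExperiment
#'   summary followed by four lines for `rowLinks`, `rowTree`, `colLinks`
#'   and `colTree`.
#' @param object A `TreeExperiment`.
setMethod("show", "TreeExperiment", function(object) {
  methods::callNextMethod()
  cat(.tl_links_line("rowLinks", object@rowLinks), "\n",
      .tl_tree_line("rowTree", object@rowTree), "\n",
      .tl_links_line("colLinks", object@colLinks), "\n",
      .tl_tree_line("colTree", object@colTree), "\n", sep = "")
})
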