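# Subsetting, tree replacement and node-based extraction.

# normalize an index (numeric/logical/character) to positive positions
.tl_norm_index <- function(i, n, nms, what) {
  pos <- seq_len(n)
  names(pos) <- nms
  out <- tryCatch(unname(pos[i]), error = function(e) NA_integer_)
  if (is.null(out))
    out <- integer(0L)
  if (anyNA(out))
    .tl_stop_val("out-of-range ", what, " indices")
  out
}

#' @describeIn subsetByNode Index subsetting (`x[i, j]`): assays,
#'   annotation tables, link tables and reference sequences are subset in
#'   lockstep; the trees are kept untouched (no pruning), so node numbers
#'   in the link tables stay valid.
#' @param i,j Row and column indices.
#' @param ... Passed to the SummarizedExperiment method.
#' @param drop Ignored (kept for compatibility).
#' @export
setMethod("[", c("TreeExperiment", "ANY", "ANY"),
          function(x, i, j, ..., drop = FALSE) {
  rl <- x@rowLinks
  cl <- x@colLinks
  rs <- x@referenceSeq
  if (!missing(i)) {
    ii <- .tl_norm_index(i, nrow(x), rownames(x), "row")
    if (!is.null(rl)) rl <- rl[ii, , drop = FALSE]
    if (!is.null(rs)) rs <- rs[ii]
  }
  if (!missing(j)) {
    jj <- .tl_norm_index(j, ncol(x), colnames(x), "column")
    if (!is.null(cl)) cl <- cl[jj, , drop = FALSE]
  }
  out <- methods::callNextMethod()
  out@rowLinks <- rl
  out@colLinks <- cl
  out@referenceSeq <- rs
  methods::validObject(out)
  out
})

#' Subset a TreeExperiment by tree nodes
#'
#' Keeps exactly the rows (columns) whose linked node is among the given
#' node set, preserving the original order. The trees themselves are not
#' pruned, so node identities remain stable; several rows mapping to one
#' node are all retained.
#'
#' @param x A [TreeExperiment-class].
#' @param rowNode,colNode Node references (numbers or labels) into the
#'   row/column tree; `NULL` leaves that dimension untouched.
#' @return The subset container.
#'
#' @examples
#' tse <- toy_fixture()
#' subsetByNode(tse, rowNode = "t3")  # keeps the two rows linked to t3
#'
#' @export
subsetByNode <- function(x, rowNode = NULL, colNode = NULL) {
  stopifnot(methods::is(x, "TreeExperiment"))
  i <- seq_len(nrow(x))
  j <- seq_len(ncol(x))
  if (!is.null(rowNode)) {
    if (is.null(x@rowTree))
      .tl_stop_val("no row tree to subset by")
    num <- resolve_node(x@rowTree, rowNode)
    i <- which(x@rowLinks$nodeNum %in% num)
  }
  if (!is.null(colNode)) {
    if (is.null(x@colTree))
      .tl_stop_val("no column tree to subset by")
    num <- resolve_node(x@colTree, colNode)
    j <- which(x@colLinks$nodeNum %in% num)
  }
  x[i, j]
}

# core re-linking for one dimension; returns the updated container
.tl_relink <- function(x, tree, lab, margin) {
  .tl_validate(tree)
  len <- if (margin == 1L) nrow(x) else ncol(x)
  what <- if (margin == 1L) "row" else "column"
  if (length(lab) != len)
    .tl_stop_val(what, " node labels have length ", length(lab),
                 " but the container has ", len, " ", what, "s")
  num <- .tl_match_labels(tree, lab)
  keep <- !is.na(num)
  if (!any(keep))
    .tl_stop_val("none of the ", len, " ", what,
                 "s could be matched to the tree")
  if (!all(keep)) {
    warning(sum(!keep), " ", what,
            "(s) couldn't be matched to the tree and are/is removed.",
            call. = FALSE)
    x <- if (margin == 1L) x[keep, ] else x[, keep]
    num <- num[keep]
  }
  nms <- if (margin == 1L) rownames(x) else colnames(x)
  links <- .tl_links(tree, num, row_names = nms)
  if (margin == 1L) {
    x@rowTree <- tree
    x@rowLinks <- links
  } else {
    x@colTree <- tree
    x@colLinks <- links
  }
  methods::validObject(x)
  x
}

#' Replace the tree of a TreeExperiment
#'
#' Swaps in a new row and/or column tree and rebuilds the link tables.
#' Rows (columns) are matched to the new tree by `rowNodeLab`
#' (`colNodeLab`) when given, by the current link labels when links
#' exist, and by the dimension names otherwise; unmatched entries are
#' dropped from all aligned components with a warning.
#'
#' @inheritParams TreeExperiment
#' @param x A [TreeExperiment-class].
#' @return The container with the new tree(s) and rebuilt links.
#'
#' @examples
#' tse <- toy_fixture()
#' taxa_tree <- to_tree(as.data.frame(SummarizedExperiment::rowData(tse)))
#' changeTree(tse, rowTree = taxa_tree,
#'            rowNodeLab = SummarizedExperiment::rowData(tse)$OTU)
#'
#' @export
changeTree <- function(x, rowTree = NULL, rowNodeLab = NULL,
                       colTree = NULL, colNodeLab = NULL) {
  stopifnot(methods::is(x, "TreeExperiment"))
  if (!is.null(rowTree)) {
    lab <- rowNodeLab
    if (is.null(lab))
      lab <- if (!is.null(x@rowLinks)) x@rowLinks$nodeLab else rownames(x)
    if (is.null(lab))
      .tl_stop_val("no row names or rowNodeLab to match the row tree by")
    x <- .tl_relink(x, rowTree, as.character(lab), 1L)
  }
  if (!is.null(colTree)) {
    lab <- colNodeLab
    if (is.null(lab))
      lab <- if (!is.null(x@colLinks)) x@colLinks$nodeLab else colnames(x)
    if (is.null(lab))
      .tl_stop_val("no column names or colNodeLab to match the column tree by")
    x <- .tl_relink(x, colTree, as.character(lab), 2L)
  }
  x
}

#' Set or clear the row/column tree
#'
#' Setting `NULL` clears both the tree and its link table; setting a tree
#' delegates to [changeTree()] (matching by `nodeLab` when given, else by
#' the current links, else by the dimension names).
#'
#' @param x A [TreeExperiment-class].
#' @param tree A `phylo` tree or `NULL`.
#' @param nodeLab Optional matching labels, one per row/column.
#' @return The modified container.
#' @export
setRowTree <- function(x, tree, nodeLab = NULL) {
  stopifnot(methods::is(x, "TreeExperiment"))
  if (is.null(tree)) {
    x@rowTree <- NULL
    x@rowLinks <- NULL
    methods::validObject(x)
    return(x)
  }
  changeTree(x, rowTree = tree, rowNodeLab = nodeLab)
}

#' @rdname setRowTree
#' @export
setColTree <- function(x, tree, nodeLab = NULL) {
  stopifnot(methods::is(x, "TreeExperiment"))
  if (is.null(tree)) {
    x@colTree <- NULL
    x@colLinks <- NULL
    methods::validObject(x)
    return(x)
  }
  changeTree(x, colTree = tree, colNodeLab = nodeLab)
}

#' Subset by leaves, pruning the row tree
#'
#' Keeps the rows linked to the requested leaves and, unlike
#' [subsetByNode()], also prunes the row tree down to those leaves.
#' Because pruning renumbers nodes, the original nodes are tracked via
#' alias labels ([track_node()]) through the pruning, and the links are
#' rebuilt against the pruned tree.
#'
#' @param x A [TreeExperiment-class] with a row tree.
#' @param rowLeaf Leaf references (labels or numbers) of the row tree.
#' @return The subset container with a pruned row tree.
#'
#' @examples
#' tse <- toy_fixture()
#' subsetByLeaf(tse, c("t2", "t3"))
#'
#' @export
subsetByLeaf <- function(x, rowLeaf) {
  stopifnot(methods::is(x, "TreeExperiment"))
  if (is.null(x@rowTree))
    .tl_stop_val("no row tree to subset by")
  old <- x@rowTree
  num <- resolve_node(old, rowLeaf)
  if (any(num > .tl_ntip(old)))
    .tl_stop_val("not leaves of the row tree: ",
                 paste(.tl_label_or_alias(old, num[num > .tl_ntip(old)]),
                       collapse = ", "))
  sse <- subsetByNode(x, rowNode = num)
  if (nrow(sse) == 0L)
    .tl_stop_val("no rows are linked to the requested leaves")
  new_tree <- keep_tips(old, num)
  # identical pruning of the alias-tracked copy maps old nodes to new
  tracked <- keep_tips(track_node(old), num)
  new_num <- resolve_node(tracked, sse@rowLinks$nodeLab_alias)
  new_lab <- .tl_label_or_alias(new_tree, new_num)
  changeTree(sse, rowTree = new_tree, rowNodeLab = new_lab)
}
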