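#' Label unlabeled nodes of a tree
#'
#' Fills in missing labels using a format string in which `{number}` is
#' replaced by the node number (default `"Node_{number}"`). Existing
#' labels are never touched, and label uniqueness is re-validated.
#'
#' @param tree A `phylo` tree.
#' @param on Which nodes are in scope: `"internal"`, `"leaf"` or `"all"`.
#' @param format Label template containing `{number}`.
#' @return The labeled tree (numbering unchanged).
#' @export
add_label <- function(tree, on = c("internal", "leaf", "all"),
                      format = "Node_{number}") {
  on <- match.arg(on)
  .tl_validate(tree)
  n_tip <- .tl_ntip(tree)
  n <- .tl_nnode(tree)
  scope <- switch(on,
                  internal = (n_tip + 1L):n,
                  leaf = seq_len(n_tip),
                  all = seq_len(n))
  labs <- .tl_labels(tree)
  fill <- scope[!nzchar(labs[scope])]
  labs[fill] <- vapply(fill, function(v)
    gsub("{number}", v, format, fixed = TRUE), character(1L))
  tree$tip.label <- labs[seq_len(n_tip)]
  nl <- labs[(n_tip + 1L):n]
  if (any(nzchar(nl)))
    tree$node.label <- nl
  .tl_validate(tree)
  tree
}

#' Track nodes across pruning via alias labels
#'
#' Returns a copy of the tree in which every node (tip and internal) is
#' relabeled `alias_{number}` under the current numbering. Pruning the
#' tracked copy alongside the original lets any surviving node be
#' recovered by its alias label even though pruning renumbers nodes.
#'
#' @param tree A `phylo` tree.
#' @return The relabeled tree.
#'
#' @examples
#' tr <- parse_newick("((sample1,sample2)GroupA,(sample3,sample4)GroupB)All;")
#' track_node(tr)$node.label  # "alias_5" "alias_6" "alias_7"
#'
#' @export
track_node <- function(tree) {
  .tl_validate(tree)
  n_tip <- .tl_ntip(tree)
  n <- .tl_nnode(tree)
  tree$tip.label <- .tl_alias(seq_len(n_tip))
  tree$node.label <- .tl_alias((n_tip + 1L):n)
  tree
}

#' Prune a tree to a set of tips
#'
#' Retains the named tips (labels kept), suppresses internal nodes left
#' with a single child (summing their branch lengths), and recomputes the
#' canonical numbering.
#'
#' @param tree A `phylo` tree.
#' @param tips Tip references (numbers or labels); at least one, all of
#'   them tips.
#' @return The pruned tree.
#' @export
keep_tips <- function(tree, tips) {
  .tl_validate(tree)
  num <- resolve_node(tree, tips)
  if (length(num) == 0L)
    stop("`tips` must retain at least one tip", call. = FALSE)
  n_tip <- .tl_ntip(tree)
  if (any(num > n_tip))
    stop("not a tip: ",
         paste(.tl_label_or_alias(tree, num[num > n_tip]), collapse = ", "),
         call. = FALSE)
  num <- unique(num)
  if (length(num) == n_tip)
    return(.tl_canonical(tree))
  if (length(num) == 1L) {
    # degenerate two-node tree: the kept tip hanging off the old root
    len <- if (is.null(tree$edge.length)) NULL else
      sum(.tl_edge_len(tree)[.tl_root_path(tree, num)], na.rm = TRUE)
    phy <- list(edge = matrix(c(2L, 1L), nrow = 1L), Nnode = 1L,
                tip.label = tree$tip.label[num])
    if (!is.null(len))
      phy$edge.length <- len
    rl <- .tl_labels(tree)[.tl_root(tree)]
    if (nzchar(rl))
      phy$node.label <- rl
    class(phy) <- "phylo"
    attr(phy, "order") <- "cladewise"
    return(phy)
  }
  out <- ape::keep.tip(tree, tip = num)
  .tl_validate(.tl_canonical(out))
}

#' Collapse internal nodes into leaves
#'
#' Removes all descendants of each given internal node, turning the node
#' itself into a tip that retains its label; the numbering is recomputed.
#'
#' @param tree A `phylo` tree.
#' @param node Internal node references; none may be an ancestor of
#'   another. Unlabeled nodes are rejected (a tip must carry a label);
#'   use [add_label()] or [track_node()] first.
#' @return The collapsed tree.
#' @export
as_leaf <- function(tree, node) {
  .tl_validate(tree)
  num <- unique(resolve_node(tree, node))
  if (length(num) == 0L)
    return(.tl_canonical(tree))
  n_tip <- .tl_ntip(tree)
  if (any(num <= n_tip))
    stop("node(s) already leaves: ",
         paste(.tl_label_or_alias(tree, num[num <= n_tip]), collapse = ", "),
         call. = FALSE)
  labs <- .tl_labels(tree)
  if (any(!nzchar(labs[num])))
    stop("cannot turn unlabeled node(s) into leaves (numbers: ",
         paste(num[!nzchar(labs[num])], collapse = ", "),
         "); label them first with add_label() or track_node()",
         call. = FALSE)
  desc <- lapply(num, .tl_descendants, tree = tree)
  if (any(num %in% unlist(desc)))
    stop("nodes must not be ancestors of one another", call. = FALSE)
  kids <- .tl_kids(tree)
  drop <- unlist(desc)
  for (v in num)
    kids[[v]] <- integer(0L)
  # re-index the surviving nodes compactly for the builder
  keep <- setdiff(seq_len(.tl_nnode(tree)), drop)
  new_id <- integer(.tl_nnode(tree))
  new_id[keep] <- seq_along(keep)
  kids2 <- lapply(kids[keep], function(ch) new_id[ch])
  lens <- .tl_edge_len(tree)
  if (is.null(tree$edge.length))
    lens <- NULL
  phy <- .tl_build(kids2, new_id[.tl_root(tree)], labs[keep],
                   if (is.null(lens)) NULL else lens[keep])
  .tl_validate(phy)
}
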