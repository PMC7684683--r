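#' Convert between node labels and node numbers
#'
#' Translates node references order-preservingly. With `to = "auto"`
#' (default) numeric input is converted to labels and character input to
#' numbers, mirroring the usual interactive use.
#'
#' @param tree A `phylo` tree.
#' @param node Node numbers, labels, or a mix (list).
#' @param to One of `"auto"`, `"label"`, `"number"`.
#'
#' @return An integer vector of node numbers, or a character vector of
#'   labels (`NA` for unlabeled internal nodes).
#'
#' @examples
#' tr <- parse_newick("((sample1,sample2)GroupA,(sample3,sample4)GroupB)All;")
#' convert_node(tr, c("GroupA", "GroupB"))   # 6 7
#' convert_node(tr, c(6, 7))                 # "GroupA" "GroupB"
#'
#' @export
convert_node <- function(tree, node, to = c("auto", "label", "number")) {
  to <- match.arg(to)
  if (to == "auto")
    to <- if (is.numeric(node)) "label" else "number"
  num <- resolve_node(tree, node)
  if (to == "number")
    return(num)
  lab <- .tl_labels(tree)[num]
  lab[!nzchar(lab)] <- NA_character_
  lab
}

#' Find the descendants of a node
#'
#' @param tree A `phylo` tree.
#' @param node A single node reference (number or label).
#' @param only_leaf Restrict the result to leaves.
#' @param self_include Also include the node itself; a leaf then returns
#'   itself even with `only_leaf = TRUE`.
#'
#' @return Node numbers in ascending order.
#'
#' @examples
#' tr <- parse_newick("((t3,t2),((t1,t5),t4));")
#' find_descendant(tr, 8)                    # 3 4 5 9
#' find_descendant(tr, 8, only_leaf = TRUE)  # 3 4 5
#'
#' @export
find_descendant <- function(tree, node, only_leaf = FALSE,
                            self_include = FALSE) {
  v <- resolve_node(tree, node)
  if (length(v) != 1L)
    stop("`node` must be a single node reference", call. = FALSE)
  out <- .tl_descendants(tree, v)
  if (self_include)
    out <- c(out, v)
  if (only_leaf)
    out <- out[out <= .tl_ntip(tree)]
  sort(unique(out))
}

#' Find the children of a node
#'
#' @inheritParams find_descendant
#' @return Child node numbers in stored order (empty for a leaf).
#' @export
find_child <- function(tree, node) {
  v <- resolve_node(tree, node)
  if (length(v) != 1L)
    stop("`node` must be a single node reference", call. = FALSE)
  .tl_kids(tree)[[v]]
}

#' Find an ancestor of a node
#'
#' Walks `level` edges towards the root.
#'
#' @inheritParams find_descendant
#' @param level Number of rootward steps (positive integer).
#' @return The ancestor's node number.
#' @export
find_ancestor <- function(tree, node, level = 1L) {
  v <- resolve_node(tree, node)
  if (length(v) != 1L)
    stop("`node` must be a single node reference", call. = FALSE)
  if (length(level) != 1L || level < 1L || level != as.integer(level))
    stop("`level` must be a positive integer", call. = FALSE)
  par <- .tl_parents(tree)
  for (k in seq_len(level)) {
    if (par[v] == 0L)
      stop("ancestor level ", level, " walks past the root", call. = FALSE)
    v <- par[v]
  }
  v
}

#' Find the siblings of a node
#'
#' @inheritParams find_descendant
#' @return The other children of the node's parent (empty for the root).
#' @export
find_sibling <- function(tree, node) {
  v <- resolve_node(tree, node)
  if (length(v) != 1L)
    stop("`node` must be a single node reference", call. = FALSE)
  par <- .tl_parents(tree)
  if (par[v] == 0L)
    return(integer(0L))
  ch <- .tl_kids(tree)[[par[v]]]
  ch[ch != v]
}

#' Lowest common ancestor of a set of nodes
#'
#' Returns the first node shared by the root-paths of all given nodes
#' (the deepest common ancestor); a single node shares itself.
#'
#' @param tree A `phylo` tree.
#' @param node Node references (non-empty).
#' @return A node number.
#' @export
share_node <- function(tree, node) {
  num <- resolve_node(tree, node)
  if (length(num) == 0L)
    stop("`node` must be non-empty", call. = FALSE)
  paths <- lapply(num, function(v) .tl_root_path(tree, v))
  common <- Reduce(intersect, paths)
  # root-paths are ordered node -> root, so the first shared entry of any
  # path is the deepest common ancestor
  paths[[1L]][match(TRUE, paths[[1L]] %in% common)]
}

#' Union of descendant leaves
#'
#' @param tree A `phylo` tree.
#' @param node Node references.
#' @return Ascending, duplicate-free tip numbers descending from (or
#'   equal to) any of the given nodes.
#' @export
union_leaf <- function(tree, node) {
  num <- resolve_node(tree, node)
  n_tip <- .tl_ntip(tree)
  out <- unlist(lapply(num, function(v) {
    if (v <= n_tip) v else .tl_descendants(tree, v)
  }))
  sort(unique(out[out <= n_tip]))
}

#' Replace complete sibling sets by their ancestor
#'
#' Repeatedly replaces, within the node set, any complete set of children
#' of an internal node by that node, until no replacement is possible.
#' The descendant-leaf union of the set is preserved exactly.
#'
#' @param tree A `phylo` tree.
#' @param node Node references.
#' @return Ascending node numbers of the minimal equivalent set.
#'
#' @examples
#' tr <- parse_newick("((t3,t2),((t1,t5),t4));")
#' join_node(tr, c(3, 4, 5))  # 8
#'
#' @export
join_node <- function(tree, node) {
  s <- unique(resolve_node(tree, node))
  kids <- .tl_kids(tree)
  internals <- which(lengths(kids) > 0L)
  repeat {
    changed <- FALSE
    for (v in internals) {
      ch <- kids[[v]]
      if (all(ch %in% s)) {
        s <- unique(c(s[!(s %in% ch)], v))
        changed <- TRUE
      }
    }
    if (!changed)
      break
  }
  sort(s)
}

#' Distance between two nodes
#'
#' Sum of branch lengths along the unique path between two nodes; unit
#' branch lengths are assumed when the tree stores none.
#'
#' @param tree A `phylo` tree.
#' @param a,b Single node references.
#' @return A non-negative number.
#' @export
dist_node <- function(tree, a, b) {
  va <- resolve_node(tree, a)
  vb <- resolve_node(tree, b)
  if (length(va) != 1L || length(vb) != 1L)
    stop("`a` and `b` must be single node references", call. = FALSE)
  if (va == vb)
    return(0)
  anc <- share_node(tree, c(va, vb))
  len <- .tl_edge_len(tree)
  par <- .tl_parents(tree)
  walk <- function(v) {
    d <- 0
    while (v != anc) {
      d <- d + len[v]
      v <- par[v]
    }
    d
  }
  walk(va) + walk(vb)
}

#' Path matrix of a tree
#'
#' One row per tip, giving the node numbers on the path from that tip up
#' to the root; shorter paths are padded with `NA`.
#'
#' @param tree A `phylo` tree.
#' @return An integer matrix with `n_tips` rows, rownames the tip labels.
#' @export
mat_tree <- function(tree) {
  n_tip <- .tl_ntip(tree)
  paths <- lapply(seq_len(n_tip), function(v) .tl_root_path(tree, v))
  width <- max(lengths(paths))
  m <- t(vapply(paths, function(p) c(p, rep(NA_integer_, width - length(p))),
                integer(width)))
  rownames(m) <- tree$tip.label
  colnames(m) <- paste0("L", seq_len(width))
  m
}

#' Test whether nodes are leaves
#'
#' @param tree A `phylo` tree.
#' @param node Node references.
#' @return A logical vector.
#' @export
is_leaf <- function(tree, node) {
  resolve_node(tree, node) <= .tl_ntip(tree)
}

#' Count the nodes of a tree
#'
#' @param tree A `phylo` tree.
#' @return Total number of nodes (tips plus internals).
#' @export
count_node <- function(tree) {
  .tl_nnode(tree)
}

#' List the node numbers of a tree
#'
#' @param tree A `phylo` tree.
#' @param only_leaf Return tip numbers only.
#' @return Ascending node numbers.
#' @export
show_node <- function(tree, only_leaf = FALSE) {
  if (only_leaf) seq_len(.tl_ntip(tree)) else seq_len(.tl_nnode(tree))
}

#' Tabulate node information
#'
#' @param tree A `phylo` tree.
#' @param type Which nodes to report.
#' @return A data frame with columns `nodeLab` (`NA` when unlabeled),
#'   `nodeNum` and `isLeaf`.
#' @export
print_node <- function(tree, type = c("all", "leaf", "internal")) {
  type <- match.arg(type)
  n_tip <- .tl_ntip(tree)
  num <- switch(type,
                all = seq_len(.tl_nnode(tree)),
                leaf = seq_len(n_tip),
                internal = n_tip + seq_len(tree$Nnode))
  lab <- .tl_labels(tree)[num]
  lab[!nzchar(lab)] <- NA_character_
  data.frame(nodeLab = lab, nodeNum = num, isLeaf = num <= n_tip,
             stringsAsFactors = FALSE)
}
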