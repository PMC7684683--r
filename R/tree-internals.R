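# Internal helpers for the rooted-tree representation.
#
# Trees are ape "phylo" objects kept in a canonical form:
#   * tips are numbered 1..n_tips in order of appearance in a preorder
#     traversal (equivalently, left-to-right in the Newick string);
#   * internal nodes are numbered n_tips+1 .. n_tips+Nnode in preorder,
#     so the root is always n_tips+1;
#   * edges are stored in preorder ("cladewise") order;
#   * unlabeled internal nodes carry "" in node.label, and node.label is
#     dropped entirely when no internal node is labeled.
# Every parsed or edited tree goes through .tl_canonical() + .tl_validate()
# so downstream code can rely on this numbering.

.tl_ntip <- function(phy) length(phy$tip.label)

.tl_nnode <- function(phy) .tl_ntip(phy) + phy$Nnode

.tl_root <- function(phy) .tl_ntip(phy) + 1L

# parent of each node (0 for the root)
.tl_parents <- function(phy) {
  p <- integer(.tl_nnode(phy))
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

# children of each node, in stored (edge) order; tips get integer(0)
.tl_kids <- function(phy) {
  n <- .tl_nnode(phy)
  unname(split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(n))))
}

# labels for all nodes; "" marks an unlabeled internal node
.tl_labels <- function(phy) {
  nl <- phy$node.label
  if (is.null(nl)) nl <- rep("", phy$Nnode)
  nl[is.na(nl)] <- ""
  c(phy$tip.label, nl)
}

.tl_alias <- function(num) paste0("alias_", num, recycle0 = TRUE)

# label if present, alias otherwise
.tl_label_or_alias <- function(phy, num) {
  lab <- .tl_labels(phy)[num]
  miss <- !nzchar(lab)
  lab[miss] <- .tl_alias(num[miss])
  lab
}

# per-node length of the edge to the parent (NA at the root);
# unit lengths when the tree has none
.tl_edge_len <- function(phy) {
  len <- rep(NA_real_, .tl_nnode(phy))
  if (is.null(phy$edge.length)) {
    len[phy$edge[, 2L]] <- 1
  } else {
    len[phy$edge[, 2L]] <- phy$edge.length
  }
  len
}

# Build a canonical phylo from an adjacency description over arbitrary
# ids 1..N: `kids` a list of child-id vectors (stored order respected),
# `labels` a character vector per id ("" = unlabeled), `lens` an optional
# numeric vector per id (edge length to the parent).
.tl_build <- function(kids, root, labels, lens = NULL) {
  n_all <- length(kids)
  is_tip <- lengths(kids) == 0L
  n_tip <- sum(is_tip)
  if (n_tip < 1L)
    stop("tree has no tips", call. = FALSE)
  new_num <- integer(n_all)
  visit <- integer(n_all)
  tip_ct <- 0L
  int_ct <- n_tip
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    visit[k] <- v
    if (is_tip[v]) {
      tip_ct <- tip_ct + 1L
      new_num[v] <- tip_ct
    } else {
      int_ct <- int_ct + 1L
      new_num[v] <- int_ct
    }
    ch <- kids[[v]]
    if (length(ch))
      stack <- c(stack, rev(ch))
  }
  if (k != n_all)
    stop("tree is not connected: ", n_all - k, " unreachable node(s)",
         call. = FALSE)
  # preorder edge list: one edge per visited non-root node
  kids_only <- visit[visit != root]
  parent_of <- integer(n_all)
  for (v in seq_len(n_all)) parent_of[kids[[v]]] <- v
  edge <- cbind(new_num[parent_of[kids_only]], new_num[kids_only])
  tip.label <- character(n_tip)
  tip.label[new_num[is_tip]] <- labels[is_tip]
  node.label <- character(n_all - n_tip)
  node.label[new_num[!is_tip] - n_tip] <- labels[!is_tip]
  phy <- list(edge = edge, Nnode = n_all - n_tip, tip.label = tip.label)
  if (any(nzchar(node.label)))
    phy$node.label <- node.label
  if (!is.null(lens)) {
    el <- lens[kids_only]
    if (!all(is.na(el)))
      phy$edge.length <- el
  }
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

# Renumber an arbitrary (valid) phylo into canonical form.
.tl_canonical <- function(phy) {
  n <- .tl_nnode(phy)
  kids <- .tl_kids(phy)
  is_child <- logical(n)
  is_child[phy$edge[, 2L]] <- TRUE
  root <- which(!is_child & lengths(kids) > 0L)
  if (length(root) != 1L)
    stop("tree must have exactly one root; found ", length(root),
         call. = FALSE)
  lens <- if (is.null(phy$edge.length)) NULL else {
    l <- rep(NA_real_, n)
    l[phy$edge[, 2L]] <- phy$edge.length
    l
  }
  .tl_build(kids, root, .tl_labels(phy), lens)
}

.tl_validate <- function(phy) {
  if (!inherits(phy, "phylo"))
    stop("not a phylo tree", call. = FALSE)
  n_tip <- .tl_ntip(phy)
  tips <- phy$tip.label
  if (any(is.na(tips)) || any(!nzchar(tips)))
    stop("tip labels must be non-empty", call. = FALSE)
  if (anyDuplicated(tips))
    stop("duplicate tip labels: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "),
         call. = FALSE)
  labs <- .tl_labels(phy)
  named <- labs[nzchar(labs)]
  if (anyDuplicated(named))
    stop("duplicate node labels: ",
         paste(unique(named[duplicated(named)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0, na.rm = TRUE))
    stop("negative branch lengths", call. = FALSE)
  # each non-root node has exactly one parent
  if (anyDuplicated(phy$edge[, 2L]))
    stop("a node has more than one parent", call. = FALSE)
  n <- .tl_nnode(phy)
  is_child <- logical(n)
  is_child[phy$edge[, 2L]] <- TRUE
  if (sum(!is_child) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  invisible(phy)
}

# Resolve node references (numbers, labels, alias labels, or a list
# mixing them) to node numbers. Errors name the offending reference.
resolve_node <- function(tree, node) {
  if (is.list(node))
    return(vapply(node, function(x) resolve_node(tree, x)[1L], integer(1L)))
  if (length(node) == 0L)
    return(integer(0L))
  n <- .tl_nnode(tree)
  if (is.numeric(node)) {
    num <- as.integer(node)
    if (any(is.na(num)) || any(num != node))
      stop("node numbers must be whole numbers", call. = FALSE)
    bad <- num < 1L | num > n
    if (any(bad))
      stop("node number(s) not in tree: ",
           paste(num[bad], collapse = ", "), call. = FALSE)
    return(num)
  }
  if (!is.character(node))
    stop("node references must be numbers or labels", call. = FALSE)
  num <- .tl_match_labels(tree, node)
  if (anyNA(num))
    stop("unknown node label(s): ",
         paste(node[is.na(num)], collapse = ", "), call. = FALSE)
  num
}

# Vectorized label -> number lookup; real labels take precedence over
# alias labels; NA where unmatched.
.tl_match_labels <- function(tree, lab) {
  labs <- .tl_labels(tree)
  idx <- seq_along(labs)
  map <- stats::setNames(idx[nzchar(labs)], labs[nzchar(labs)])
  num <- unname(map[lab])
  miss <- is.na(num) & grepl("^alias_[0-9]+$", lab)
  if (any(miss)) {
    cand <- as.integer(sub("^alias_", "", lab[miss]))
    cand[cand < 1L | cand > length(labs)] <- NA_integer_
    num[miss] <- cand
  }
  as.integer(num)
}

# all strict descendants of `num` (any order)
.tl_descendants <- function(tree, num) {
  kids <- .tl_kids(tree)
  out <- integer(0L)
  stack <- kids[[num]]
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  out
}

# path from a node to the root, inclusive
.tl_root_path <- function(tree, num) {
  par <- .tl_parents(tree)
  path <- num
  v <- num
  while (par[v] != 0L) {
    v <- par[v]
    path <- c(path, v)
  }
  path
}
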