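# Brute-force oracles working directly on the phylo edge matrix,
# independent of the package's internal traversal code.

oracle_children <- function(phy, v) phy$edge[phy$edge[, 1] == v, 2]

oracle_parent <- function(phy, v) {
  p <- phy$edge[phy$edge[, 2] == v, 1]
  if (length(p)) p else NA_integer_
}

# reachability by repeated edge expansion
oracle_descendants <- function(phy, v) {
  out <- integer(0)
  frontier <- v
  repeat {
    nxt <- phy$edge[phy$edge[, 1] %in% frontier, 2]
    nxt <- setdiff(nxt, out)
    if (!length(nxt))
      break
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

oracle_root_path <- function(phy, v) {
  path <- v
  while (!is.na(p <- oracle_parent(phy, v))) {
    path <- c(path, p)
    v <- p
  }
  path
}

oracle_lca <- function(phy, nodes) {
  paths <- lapply(nodes, function(v) oracle_root_path(phy, v))
  common <- Reduce(intersect, paths)
  paths[[1]][paths[[1]] %in% common][1]
}

oracle_leaf_union <- function(phy, nodes) {
  n_tip <- length(phy$tip.label)
  sort(unique(unlist(lapply(nodes, function(v)
    intersect(c(v, oracle_descendants(phy, v)), seq_len(n_tip))))))
}

# path length between two nodes via the LCA
oracle_dist <- function(phy, a, b) {
  len <- rep(1, max(phy$edge))
  if (!is.null(phy$edge.length))
    len[phy$edge[, 2]] <- phy$edge.length
  anc <- oracle_lca(phy, c(a, b))
  up <- function(v) {
    d <- 0
    while (v != anc) {
      d <- d + len[v]
      v <- oracle_parent(phy, v)
    }
    d
  }
  up(a) + up(b)
}
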