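#' Detect polyphyletic loops in a taxonomy table
#'
#' A taxonomy table has one ordered rank column per level (broad to fine)
#' and one row per entity. A "loop" is a child value that appears under
#' two or more distinct parent values in the adjacent broader column
#' (`NA` counts as a distinct value, for parents and children alike);
#' such tables cannot be converted into a tree until resolved.
#'
#' @param tab A data frame (or `DataFrame`) of ordered rank columns.
#' @return A data frame with columns `parent`, `child`, `parent_column`,
#'   `child_column`, one row per offending parent/child pair; zero rows
#'   when the table is loop-free.
#'
#' @seealso [resolve_loop()], [to_tree()]
#' @export
detect_loop <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  empty <- data.frame(parent = character(0L), child = character(0L),
                      parent_column = character(0L),
                      child_column = character(0L),
                      stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    return(empty)
  out <- list()
  for (k in seq_len(ncol(tab) - 1L)) {
    parent <- as.character(tab[[k]])
    child <- as.character(tab[[k + 1L]])
    pairs <- unique(data.frame(parent = parent, child = child,
                               stringsAsFactors = FALSE))
    # NA children/parents are distinct values of their own
    key <- ifelse(is.na(pairs$child), "\r<NA>", pairs$child)
    multi <- names(which(table(key) >= 2L))
    if (length(multi)) {
      hit <- pairs[key %in% multi, , drop = FALSE]
      hit$parent_column <- colnames(tab)[k]
      hit$child_column <- colnames(tab)[k + 1L]
      out[[length(out) + 1L]] <- hit
    }
  }
  if (!length(out))
    return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve polyphyletic loops by suffixing child values
#'
#' Every looping (non-missing) child value is suffixed `_{k}` where
#' `k = 1..m` numbers its distinct parent values in order of first
#' appearance, so that e.g. a genus found under two families becomes
#' `Genus_1` and `Genus_2`. Columns are processed broad to fine, so
#' suffixes introduced at one rank are taken into account when checking
#' the next. Missing cells are left untouched; non-looping cells are
#' unchanged; the operation is idempotent.
#'
#' @inheritParams detect_loop
#' @return The resolved table, same shape and dimnames.
#' @export
resolve_loop <- function(tab) {
  was_df <- methods::is(tab, "DataFrame")
  res <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (nrow(res) == 0L || ncol(res) < 2L)
    return(if (was_df) S4Vectors::DataFrame(res) else res)
  for (k in seq_len(ncol(res) - 1L)) {
    parent <- as.character(res[[k]])
    child <- as.character(res[[k + 1L]])
    pkey <- ifelse(is.na(parent), "\r<NA>", parent)
    for (val in unique(child[!is.na(child)])) {
      rows <- which(!is.na(child) & child == val)
      pars <- unique(pkey[rows])
      if (length(pars) >= 2L) {
        suffix <- match(pkey[rows], pars)
        res[[k + 1L]][rows] <- paste0(val, "_", suffix)
      }
    }
  }
  if (was_df) S4Vectors::DataFrame(res) else res
}

#' Convert a taxonomy table into a tree
#'
#' Builds a rooted tree whose leaves are the final-column values
#' (unprefixed) and whose internal nodes are labeled `"{rank}:{value}"`.
#' Consecutive identical paths merge into shared internal nodes; a run of
#' missing values below a named rank is bridged, so the leaf attaches to
#' its deepest named ancestor. When more than one top-level value is
#' present a synthetic root labeled `"ALL"` is added. Branch lengths are
#' set to one. Leaves are numbered `1..n` in row order (after dropping
#' duplicated rows) and internal nodes in preorder.
#'
#' @inheritParams detect_loop
#' @return A `phylo` tree in canonical form.
#'
#' @examples
#' tax <- data.frame(Phylum = c("B1", "B1", "B2"),
#'                   OTU = c("D1", "D2", "D3"))
#' to_tree(tax)$node.label
#'
#' @export
to_tree <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (ncol(tab) < 1L || nrow(tab) < 1L)
    .tl_stop_val("taxonomy table must have at least one row and column")
  loops <- detect_loop(tab)
  loops <- loops[!is.na(loops$child), , drop = FALSE]
  if (nrow(loops) > 0L)
    .tl_stop_val("taxonomy table contains polyphyletic loops (e.g. child '",
                 loops$child[1L], "' under parents '",
                 paste(unique(loops$parent[loops$child == loops$child[1L]]),
                       collapse = "', '"),
                 "'); run resolve_loop() first")
  ranks <- colnames(tab)
  leaf_col <- ncol(tab)
  if (anyNA(tab[[leaf_col]]))
    .tl_stop_val("final taxonomy column (leaf labels) contains missing values")
  tab <- tab[!duplicated(tab), , drop = FALSE]
  leaves <- as.character(tab[[leaf_col]])
  if (anyDuplicated(leaves))
    .tl_stop_val("duplicate leaf labels after de-duplication: ",
                 paste(unique(leaves[duplicated(leaves)]), collapse = ", "))
  # nodes keyed by full path so identical prefixes merge
  labels <- character(0L)
  kids <- list()
  new_node <- function(lab) {
    kids[[length(kids) + 1L]] <<- integer(0L)
    labels[length(labels) + 1L] <<- lab
    length(kids)
  }
  root <- new_node("ALL")
  path_id <- stats::setNames(root, "\r")
  for (r in seq_len(nrow(tab))) {
    parent <- root
    key <- "\r"
    for (k in seq_len(leaf_col)) {
      val <- tab[[k]][r]
      if (is.na(val))
        next                       # bridge missing ranks
      lab <- if (k == leaf_col) as.character(val)
             else paste0(ranks[k], ":", val)
      key <- paste0(key, "\r", lab)
      hit <- unname(path_id[key])
      if (is.na(hit)) {
        hit <- new_node(lab)
        kids[[parent]] <- c(kids[[parent]], hit)
        path_id[key] <- hit
      }
      parent <- hit
    }
  }
  # single top-level value: that node becomes the root
  if (length(kids[[root]]) == 1L) {
    top <- kids[[root]][1L]
    if (length(kids[[top]]) > 0L) {
      keep <- setdiff(seq_along(kids), root)
      new_id <- integer(length(kids))
      new_id[keep] <- seq_along(keep)
      kids <- lapply(kids[keep], function(ch) new_id[ch])
      labels <- labels[keep]
      root <- new_id[top]
    }
  }
  lens <- rep(1, length(kids))
  phy <- .tl_build(kids, root, labels, lens)
  .tl_validate(phy)
}
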