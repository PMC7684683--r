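#' Resolve an aggregation level to node numbers
#'
#' Node labels and node numbers may be mixed; input order is preserved
#' and duplicates are collapsed.
#'
#' @param tree A `phylo` tree.
#' @param level Node references.
#' @return Ordered, unique node numbers.
#' @export
resolve_level <- function(tree, level) {
  num <- resolve_node(tree, level)
  num[!duplicated(num)]
}

#' Collapse an annotation table over contributor groups
#'
#' For each target group and each column, the collapsed value is the one
#' shared by all contributors when they agree, and missing otherwise
#' (the metadata "remains valid" rule). Column types are preserved.
#'
#' @param table A data frame or `DataFrame`.
#' @param groups A named list of row-index vectors, one entry per target.
#' @return A table with one row per target (rownames from `names(groups)`)
#'   and the same columns and class as the input.
#' @export
collapse_metadata <- function(table, groups) {
  was_df <- methods::is(table, "DataFrame")
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  n_out <- length(groups)
  cols <- lapply(df, function(col) {
    out <- col[rep(NA_integer_, n_out)]   # NA of the column's own type
    for (g in seq_len(n_out)) {
      u <- unique(col[groups[[g]]])
      if (length(u) == 1L)
        out[g] <- u
    }
    out
  })
  res <- if (ncol(df) == 0L)
    data.frame(row.names = names(groups))
  else
    data.frame(cols, stringsAsFactors = FALSE, row.names = names(groups),
               check.names = FALSE)
  if (was_df) {
    res <- S4Vectors::DataFrame(res, check.names = FALSE)
    rownames(res) <- names(groups)
  }
  res
}

# contributor groups for one dimension: list(name=, target=, idx=, block=)
.tl_groups <- function(tree, linked, targets, block_vals) {
  n_tip <- .tl_ntip(tree)
  groups <- list()
  for (v in targets) {
    dset <- c(.tl_descendants(tree, v), v)
    idx <- which(linked %in% dset)
    alias <- .tl_alias(v)
    if (is.null(block_vals)) {
      if (length(idx) == 0L)
        warning("node ", alias, " has no contributing entries; ",
                "filled with NA", call. = FALSE)
      groups[[alias]] <- list(target = v, idx = idx, block = NULL)
    } else {
      if (length(idx) == 0L) {
        warning("node ", alias, " has no contributing entries; ",
                "filled with NA", call. = FALSE)
        groups[[alias]] <- list(target = v, idx = idx, block = NULL)
        next
      }
      bv <- block_vals[idx]
      for (b in unique(bv)) {
        nm <- paste0(alias, ".", b)
        groups[[nm]] <- list(target = v, idx = idx[bv == b], block = b)
      }
    }
  }
  groups
}

# reduce one assay over groups along one margin
.tl_reduce <- function(mat, groups, fun, margin, what) {
  n_opp <- if (margin == 1L) ncol(mat) else nrow(mat)
  out <- matrix(NA_real_, nrow = length(groups), ncol = n_opp)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]$idx
    if (length(idx) == 0L)
      next
    for (j in seq_len(n_opp)) {
      vals <- if (margin == 1L) mat[idx, j] else mat[j, idx]
      r <- tryCatch(fun(vals), error = function(e)
        .tl_stop_val("reducer failed on ", what, " target ",
                     names(groups)[g], ": ", conditionMessage(e)))
      if (length(r) != 1L)
        .tl_stop_val("reducer returned length ", length(r), " on ", what,
                     " target ", names(groups)[g])
      out[g, j] <- r
    }
  }
  if (margin == 1L) {
    rownames(out) <- names(groups)
    colnames(out) <- colnames(mat)
    out
  } else {
    t_out <- t(out)
    rownames(t_out) <- rownames(mat)
    colnames(t_out) <- names(groups)
    t_out
  }
}

.tl_agg_dim <- function(x, level, fun, block, margin, message = FALSE) {
  what <- if (margin == 1L) "row" else "column"
  tree <- if (margin == 1L) x@rowTree else x@colTree
  links <- if (margin == 1L) x@rowLinks else x@colLinks
  if (is.null(tree))
    .tl_stop_val("no ", what, " tree to aggregate over")
  targets <- resolve_level(tree, level)
  block_vals <- NULL
  if (!is.null(block)) {
    ann <- if (margin == 1L) SummarizedExperiment::rowData(x) else
      SummarizedExperiment::colData(x)
    if (!block %in% colnames(ann))
      .tl_stop_val("block column '", block, "' not found in ", what, " data")
    block_vals <- ann[[block]]
  }
  groups <- .tl_groups(tree, links$nodeNum, targets, block_vals)
  if (message)
    message("aggregating ", length(groups), " ", what, " group(s) over ",
            length(targets), " node(s)")
  idx_list <- lapply(groups, `[[`, "idx")
  new_assays <- lapply(SummarizedExperiment::assays(x), .tl_reduce,
                       groups = groups, fun = fun, margin = margin,
                       what = what)
  tnum <- vapply(groups, `[[`, integer(1L), "target")
  new_links <- .tl_links(tree, tnum, row_names = names(groups))
  if (margin == 1L) {
    new_rd <- collapse_metadata(SummarizedExperiment::rowData(x), idx_list)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = new_assays, rowData = new_rd,
      colData = SummarizedExperiment::colData(x),
      metadata = S4Vectors::metadata(x))
    rownames(se) <- names(groups)
    methods::new("TreeExperiment", se,
                 rowTree = tree, rowLinks = new_links,
                 colTree = x@colTree, colLinks = x@colLinks,
                 referenceSeq = NULL)
  } else {
    new_cd <- collapse_metadata(SummarizedExperiment::colData(x), idx_list)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = new_assays, rowData = SummarizedExperiment::rowData(x),
      colData = new_cd, metadata = S4Vectors::metadata(x))
    colnames(se) <- names(groups)
    methods::new("TreeExperiment", se,
                 rowTree = x@rowTree, rowLinks = x@rowLinks,
                 colTree = tree, colLinks = new_links,
                 referenceSeq = x@referenceSeq)
  }
}

#' Aggregate assay data to arbitrary tree nodes
#'
#' For every target node, the contributing rows (columns) are those whose
#' linked node lies in the target's descendant-or-self set; the reducer
#' is applied to the contributing values independently for each position
#' of the opposing dimension. Overlapping targets each independently
#' include shared contributors, and entries under no target are simply
#' absent from the output. Output dimension names are the targets' alias
#' labels (`alias_{nodeNum}`); annotation tables are collapsed with
#' [collapse_metadata()] and links are rebuilt to point at the targets.
#'
#' With `rowBlock` set, rows are reduced separately within each value of
#' that row-annotation column: the output contains one row per
#' (target, block value) pair present among the target's contributors,
#' named `alias_{nodeNum}.{block}`.
#'
#' @param x A [TreeExperiment-class] with the relevant tree(s).
#' @param rowLevel,colLevel Target node sets (labels or numbers); at
#'   least one must be given.
#' @param rowFun,colFun Reducers mapping a numeric vector to one number.
#' @param rowFirst When both levels are given, aggregate rows before
#'   columns (`TRUE`, default) or columns first.
#' @param rowBlock Optional row-annotation column name to block on.
#' @param whichAssay Optional assay names to carry through (default all).
#' @param message Emit progress messages.
#' @return The aggregated container.
#'
#' @examples
#' tse <- toy_fixture()
#' agg <- aggregateByNode(tse, colLevel = c("GroupA", "GroupB"),
#'                        colFun = sum)
#' SummarizedExperiment::assay(agg)
#'
#' @export
aggregateByNode <- function(x, rowLevel = NULL, colLevel = NULL,
                            rowFun = sum, colFun = sum, rowFirst = TRUE,
                            rowBlock = NULL, whichAssay = NULL,
                            message = FALSE) {
  stopifnot(methods::is(x, "TreeExperiment"))
  if (is.null(rowLevel) && is.null(colLevel))
    .tl_stop_val("at least one of rowLevel/colLevel must be given")
  if (!is.null(whichAssay)) {
    bad <- setdiff(whichAssay, SummarizedExperiment::assayNames(x))
    if (length(bad))
      .tl_stop_val("unknown assay(s): ", paste(bad, collapse = ", "))
    SummarizedExperiment::assays(x) <-
      SummarizedExperiment::assays(x)[whichAssay]
  }
  steps <- list()
  if (!is.null(rowLevel))
    steps <- c(steps, list(function(y)
      .tl_agg_dim(y, rowLevel, rowFun, rowBlock, 1L, message)))
  if (!is.null(colLevel))
    steps <- c(steps, list(function(y)
      .tl_agg_dim(y, colLevel, colFun, NULL, 2L, message)))
  if (!rowFirst)
    steps <- rev(steps)
  for (f in steps)
    x <- f(x)
  x
}
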