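#' The worked example container
#'
#' A small fully worked container: a 6 x 4 count matrix (a zero row atop
#' the values 1..20 filled by column), a four-rank taxonomy as row
#' annotation, two sample covariates, a 5-leaf row tree
#' `((t3,t2),((t1,t5),t4));` to which the six rows map via the labels
#' `t3,t3,t2,t1,t5,t4` (two rows share leaf t3), and a labeled 4-leaf
#' column tree `((sample1,sample2)GroupA,(sample3,sample4)GroupB)All;`.
#'
#' @return A [TreeExperiment-class].
#'
#' @examples
#' toy_fixture()
#'
#' @export
toy_fixture <- function() {
  assay_data <- rbind(rep(0, 4), matrix(1:20, nrow = 5))
  colnames(assay_data) <- paste0("sample", 1:4)
  rownames(assay_data) <- paste0("entity", seq_len(6))
  row_data <- data.frame(Kingdom = "A",
                         Phylum = rep(c("B1", "B2"), c(2, 4)),
                         Class = rep(c("C1", "C2", "C3"), each = 2),
                         OTU = paste0("D", 1:6),
                         row.names = rownames(assay_data),
                         stringsAsFactors = FALSE)
  col_data <- data.frame(gg = c(1, 2, 3, 3),
                         group = rep(LETTERS[1:2], each = 2),
                         row.names = colnames(assay_data),
                         stringsAsFactors = FALSE)
  row_tree <- parse_newick("((t3,t2),((t1,t5),t4));")
  col_tree <- parse_newick(
    "((sample1,sample2)GroupA,(sample3,sample4)GroupB)All;")
  TreeExperiment(assays = list(Count = assay_data),
                 rowData = row_data, colData = col_data,
                 rowTree = row_tree,
                 rowNodeLab = c("t3", "t3", "t2", "t1", "t5", "t4"),
                 colTree = col_tree)
}

#' Random rooted tree
#'
#' Grows a binary tree by starting from a single tip and repeatedly
#' splitting a uniformly chosen tip into two, then assigns uniform (0,1]
#' branch lengths. Tips are labeled `t1..tn` in canonical numbering
#' order; internal nodes are unlabeled. Deterministic for a given seed.
#'
#' @param n_tips Number of tips (at least 2).
#' @param seed Optional integer seed; the caller's RNG state is
#'   untouched.
#' @return A `phylo` tree in canonical form.
#' @export
random_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2L)
    .tl_stop_val("n_tips must be at least 2")
  if (!is.null(seed))
    return(withr::with_seed(seed, random_tree(n_tips)))
  kids <- list(integer(0L))
  tips <- 1L
  for (s in seq_len(n_tips - 1L)) {
    u <- tips[sample.int(length(tips), 1L)]
    a <- length(kids) + 1L
    b <- length(kids) + 2L
    kids[[a]] <- integer(0L)
    kids[[b]] <- integer(0L)
    kids[[u]] <- c(a, b)
    tips <- c(tips[tips != u], a, b)
  }
  n_all <- length(kids)
  lens <- stats::runif(n_all)
  lens[lens == 0] <- .Machine$double.eps
  labels <- rep("", n_all)
  labels[lengths(kids) == 0L] <- "pending"
  phy <- .tl_build(kids, 1L, labels, lens)
  phy$tip.label <- paste0("t", seq_len(n_tips))
  .tl_validate(phy)
}

#' Random linked container
#'
#' Builds a container for property testing: a Poisson count assay, small
#' annotation tables, a column tree whose leaves are the samples, and a
#' row tree (about half as many tips as rows) to whose nodes -- leaves
#' and internals alike, addressed by alias where unlabeled -- the rows
#' are linked uniformly at random. Deterministic for a given seed.
#'
#' @param n_rows,n_cols Dimensions of the assay.
#' @param seed Optional integer seed.
#' @return A [TreeExperiment-class].
#' @export
random_container <- function(n_rows, n_cols, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, random_container(n_rows, n_cols)))
  if (n_rows < 2L || n_cols < 2L)
    .tl_stop_val("need at least 2 rows and 2 columns")
  row_tree <- random_tree(max(2L, n_rows %/% 2L))
  col_tree <- random_tree(n_cols)
  col_tree$tip.label <- paste0("sample", seq_len(n_cols))
  m <- matrix(stats::rpois(n_rows * n_cols, 10),
              nrow = n_rows,
              dimnames = list(paste0("feature", seq_len(n_rows)),
                              paste0("sample", seq_len(n_cols))))
  # uniformly chosen nodes, leaves and internals alike
  node_pool <- .tl_label_or_alias(row_tree, seq_len(.tl_nnode(row_tree)))
  row_lab <- sample(node_pool, n_rows, replace = TRUE)
  rd <- data.frame(group = sample(LETTERS[1:3], n_rows, replace = TRUE),
                   row.names = rownames(m), stringsAsFactors = FALSE)
  cd <- data.frame(batch = sample(1:2, n_cols, replace = TRUE),
                   row.names = colnames(m), stringsAsFactors = FALSE)
  TreeExperiment(assays = list(Count = m), rowData = rd, colData = cd,
                 rowTree = row_tree, rowNodeLab = row_lab,
                 colTree = col_tree,
                 colNodeLab = col_tree$tip.label[seq_len(n_cols)])
}
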