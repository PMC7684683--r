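# Directory-bundle serialization: assays/*.tsv, row_data.tsv,
# col_data.tsv, row_tree.nwk, col_tree.nwk, row_links.tsv,
# col_links.tsv, refseq.fasta, manifest.yaml.

.tl_write_table <- function(x, path, delim = "\t") {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     col.names = NA, row.names = TRUE, na = "NA")
}

.tl_read_table <- function(path, delim = "\t") {
  .tl_need_file(path)
  utils::read.delim(path, sep = delim, row.names = 1L, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.tl_need_file <- function(path) {
  if (!file.exists(path))
    .tl_stop_io("missing file: ", path)
  invisible(path)
}

#' Write a TreeExperiment as a text bundle
#'
#' Serializes the container into a directory of plain-text files: one
#' TSV per assay under `assays/`, the annotation and link tables as TSV,
#' the trees as Newick (12 significant digits), reference sequences as
#' FASTA, and a `manifest.yaml` tying them together. `metadata()` is not
#' serialized.
#'
#' @param x A [TreeExperiment-class].
#' @param dir Target directory (created if needed).
#' @param delim Field delimiter for the tables.
#' @return The manifest, invisibly.
#' @seealso [read_bundle()]
#' @export
write_bundle <- function(x, dir, delim = "\t") {
  stopifnot(methods::is(x, "TreeExperiment"))
  dir.create(file.path(dir, "assays"), recursive = TRUE,
             showWarnings = FALSE)
  nms <- SummarizedExperiment::assayNames(x)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- paste0("assay", seq_along(SummarizedExperiment::assays(x)))
  manifest <- list(format = "treelink-bundle", version = 1L,
                   delimiter = delim, assays = list())
  for (k in seq_along(nms)) {
    rel <- file.path("assays", paste0(nms[k], ".tsv"))
    .tl_write_table(SummarizedExperiment::assays(x)[[k]],
                    file.path(dir, rel), delim)
    manifest$assays[[nms[k]]] <- rel
  }
  .tl_write_table(SummarizedExperiment::rowData(x),
                  file.path(dir, "row_data.tsv"), delim)
  .tl_write_table(SummarizedExperiment::colData(x),
                  file.path(dir, "col_data.tsv"), delim)
  manifest$row_data <- "row_data.tsv"
  manifest$col_data <- "col_data.tsv"
  if (!is.null(x@rowTree)) {
    write_newick(x@rowTree, file.path(dir, "row_tree.nwk"))
    .tl_write_table(x@rowLinks, file.path(dir, "row_links.tsv"), delim)
    manifest$row_tree <- "row_tree.nwk"
    manifest$row_links <- "row_links.tsv"
  }
  if (!is.null(x@colTree)) {
    write_newick(x@colTree, file.path(dir, "col_tree.nwk"))
    .tl_write_table(x@colLinks, file.path(dir, "col_links.tsv"), delim)
    manifest$col_tree <- "col_tree.nwk"
    manifest$col_links <- "col_links.tsv"
  }
  if (!is.null(x@referenceSeq)) {
    Biostrings::writeXStringSet(x@referenceSeq,
                                file.path(dir, "refseq.fasta"))
    manifest$refseq <- "refseq.fasta"
    manifest$refseq_type <-
      if (methods::is(x@referenceSeq, "DNAStringSet")) "dna" else "plain"
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a TreeExperiment from a text bundle
#'
#' Loads a directory written by [write_bundle()] (or a hand-assembled
#' one with the same manifest). Shapes are cross-checked and errors name
#' the offending file; link tables are regenerated from the trees and
#' the stored node labels, which must reproduce the stored links.
#'
#' @param path The bundle directory, or the path of its `manifest.yaml`.
#' @return A [TreeExperiment-class].
#' @export
read_bundle <- function(path) {
  manifest_path <- if (dir.exists(path))
    file.path(path, "manifest.yaml") else path
  .tl_need_file(manifest_path)
  dir <- dirname(manifest_path)
  m <- yaml::read_yaml(manifest_path)
  delim <- if (is.null(m$delimiter)) "\t" else m$delimiter
  if (is.null(m$assays) || !length(m$assays))
    .tl_stop_io("manifest declares no assays: ", manifest_path)
  assays <- lapply(m$assays, function(rel)
    as.matrix(.tl_read_table(file.path(dir, rel), delim)))
  d <- dim(assays[[1L]])
  for (k in seq_along(assays)) {
    if (!identical(dim(assays[[k]]), d))
      .tl_stop_io("assay shape mismatch in ",
                  file.path(dir, m$assays[[k]]), ": ",
                  paste(dim(assays[[k]]), collapse = "x"), " vs ",
                  paste(d, collapse = "x"))
  }
  row_data <- .tl_read_table(file.path(dir, m$row_data), delim)
  col_data <- .tl_read_table(file.path(dir, m$col_data), delim)
  if (nrow(row_data) != d[1L])
    .tl_stop_io("row_data has ", nrow(row_data), " rows for ", d[1L],
                " assay rows: ", file.path(dir, m$row_data))
  if (nrow(col_data) != d[2L])
    .tl_stop_io("col_data has ", nrow(col_data), " rows for ", d[2L],
                " assay columns: ", file.path(dir, m$col_data))
  row_tree <- col_tree <- NULL
  row_lab <- col_lab <- NULL
  if (!is.null(m$row_tree)) {
    row_tree <- parse_newick(
      paste(readLines(.tl_need_file(file.path(dir, m$row_tree))),
            collapse = ""))
    links <- .tl_read_table(file.path(dir, m$row_links), delim)
    if (nrow(links) != d[1L])
      .tl_stop_io("row_links has ", nrow(links), " rows for ", d[1L],
                  " assay rows: ", file.path(dir, m$row_links))
    row_lab <- as.character(links$nodeLab)
  }
  if (!is.null(m$col_tree)) {
    col_tree <- parse_newick(
      paste(readLines(.tl_need_file(file.path(dir, m$col_tree))),
            collapse = ""))
    links <- .tl_read_table(file.path(dir, m$col_links), delim)
    if (nrow(links) != d[2L])
      .tl_stop_io("col_links has ", nrow(links), " rows for ", d[2L],
                  " assay columns: ", file.path(dir, m$col_links))
    col_lab <- as.character(links$nodeLab)
  }
  refseq <- NULL
  if (!is.null(m$refseq)) {
    fp <- .tl_need_file(file.path(dir, m$refseq))
    refseq <- if (identical(m$refseq_type, "dna"))
      Biostrings::readDNAStringSet(fp) else Biostrings::readBStringSet(fp)
  }
  TreeExperiment(assays = assays, rowData = row_data, colData = col_data,
                 rowTree = row_tree, rowNodeLab = row_lab,
                 colTree = col_tree, colNodeLab = col_lab,
                 referenceSeq = refseq)
}
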