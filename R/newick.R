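#' Parse a rooted tree from Newick text
#'
#' Reads a rooted Newick string (optionally with internal-node labels,
#' single-quoted labels and branch lengths) into a `phylo` tree with
#' canonical node numbering: tips are numbered `1..n_tips` in order of
#' appearance, internal nodes `n_tips+1 ..` in preorder, so the root is
#' always `n_tips + 1`.
#'
#' @param text A single Newick string, terminated by `;`.
#'
#' @return A `phylo` object in canonical form.
#'
#' @details Malformed input raises an error reporting the character offset
#' of the first offending character where it can be located (unbalanced
#' parentheses, missing terminator). Duplicate labels raise a validation
#' error: tip labels must be unique and non-empty, and internal labels,
#' where present, must be unique among all labels. Quoted labels (needed
#' e.g. for rank-prefixed taxonomy labels such as `'Phylum:B1'`) follow
#' the usual convention: single quotes, with embedded quotes doubled.
#'
#' @examples
#' tr <- parse_newick("((sample1,sample2)GroupA,(sample3,sample4)GroupB)All;")
#' count_node(tr)
#'
#' @seealso [write_newick()]
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single Newick string", call. = FALSE)
  q <- .tl_extract_quotes(text)
  .tl_check_newick_syntax(q$text)
  phy <- tryCatch(ape::read.tree(text = q$text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    .tl_stop_io("malformed Newick near character offset 1: ",
                "could not be parsed as a tree")
  if (length(q$map)) {
    restore <- function(lab) {
      hit <- match(lab, names(q$map))
      lab[!is.na(hit)] <- q$map[hit[!is.na(hit)]]
      lab
    }
    phy$tip.label <- restore(phy$tip.label)
    if (!is.null(phy$node.label))
      phy$node.label <- restore(phy$node.label)
  }
  phy <- .tl_canonical(phy)
  .tl_validate(phy)
  phy
}

# Pull single-quoted labels out of the string and substitute parse-safe
# placeholder tokens, returning the rewritten text plus the token map.
.tl_extract_quotes <- function(text) {
  map <- character(0L)
  repeat {
    m <- regexpr("'(?:[^']|'')*'", text, perl = TRUE)
    if (m == -1L)
      break
    end <- m + attr(m, "match.length") - 1L
    tok <- substr(text, m + 1L, end - 1L)
    ph <- sprintf("xQUOTEDLABELx%dx", length(map) + 1L)
    map[ph] <- gsub("''", "'", tok, fixed = TRUE)
    text <- paste0(substr(text, 1L, m - 1L), ph,
                   substr(text, end + 1L, nchar(text)))
  }
  list(text = text, map = map)
}

# Cheap structural scan so syntax errors carry a character offset.
.tl_check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  open_at <- integer(0L)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      open_at <- c(open_at, i)
    } else if (chars[i] == ")") {
      if (!length(open_at))
        .tl_stop_io("malformed Newick: unmatched ')' at character offset ", i)
      open_at <- open_at[-length(open_at)]
    }
  }
  if (length(open_at))
    .tl_stop_io("malformed Newick: unclosed '(' at character offset ",
                open_at[1L])
  if (!grepl(";", text, fixed = TRUE))
    .tl_stop_io("malformed Newick: missing ';' terminator at character ",
                "offset ", nchar(text) + 1L)
  invisible(TRUE)
}

# quote a label only when it contains characters reserved by the format
.tl_quote_label <- function(lab) {
  if (!nzchar(lab))
    return("")
  if (grepl("^[A-Za-z0-9_.|/+-]+$", lab))
    lab
  else
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
}

#' Serialize a tree to Newick text
#'
#' Writes a `phylo` tree as Newick, preserving stored child order (no
#' re-sorting) so that re-parsing reproduces the identical canonical
#' numbering. Labels containing reserved characters (such as the `:` in
#' rank-prefixed taxonomy labels) are single-quoted rather than mangled,
#' and branch lengths are written with 12 significant digits, making the
#' write/parse round trip lossless.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the Newick string is also written
#'   to this file.
#' @param digits Significant digits for branch lengths.
#'
#' @return The Newick string, invisibly when `file` is given.
#'
#' @examples
#' tr <- parse_newick("(a,b);")
#' write_newick(tr)
#'
#' @export
write_newick <- function(tree, file = NULL, digits = 12L) {
  .tl_validate(tree)
  tree <- .tl_canonical(tree)
  kids <- .tl_kids(tree)
  labs <- .tl_labels(tree)
  lens <- if (is.null(tree$edge.length)) NULL else .tl_edge_len(tree)
  branch <- function(v) {
    if (is.null(lens) || is.na(lens[v]))
      ""
    else
      paste0(":", sprintf("%.*g", digits, lens[v]))
  }
  rec <- function(v) {
    body <- if (length(kids[[v]]))
      paste0("(", paste(vapply(kids[[v]], rec, character(1L)),
                        collapse = ","), ")")
    else
      ""
    paste0(body, .tl_quote_label(labs[v]), branch(v))
  }
  txt <- paste0(rec(.tl_root(tree)), ";")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
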