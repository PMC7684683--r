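# Shared fixtures, built in code.

col_fixture_newick <- "((sample1,sample2)GroupA,(sample3,sample4)GroupB)All;"
row_fixture_newick <- "((t3,t2),((t1,t5),t4));"

col_fixture <- function() parse_newick(col_fixture_newick)
row_fixture <- function() parse_newick(row_fixture_newick)

toy_taxonomy <- function() {
  data.frame(Kingdom = "A",
             Phylum = rep(c("B1", "B2"), c(2, 4)),
             Class = rep(c("C1", "C2", "C3"), each = 2),
             OTU = paste0("D", 1:6),
             row.names = paste0("entity", 1:6),
             stringsAsFactors = FALSE)
}

taxonomy_fixture_tree <- function() to_tree(toy_taxonomy())

toy_assay <- function() {
  m <- rbind(rep(0, 4), matrix(1:20, nrow = 5))
  dimnames(m) <- list(paste0("entity", 1:6), paste0("sample", 1:4))
  m
}
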