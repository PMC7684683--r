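# Classed conditions so the CLI can map failures to exit codes
# (validation -> 1, I/O -> 2).

.tl_stop_val <- function(...) {
  stop(structure(class = c("tl_validation", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.tl_stop_io <- function(...) {
  stop(structure(class = c("tl_io", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
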