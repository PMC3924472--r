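# Classed conditions so callers (and the CLI) can distinguish bad user input
# from bad configuration without parsing message strings.

abort_input <- function(msg, ..., class = character()) {
  stop(structure(
    class = c(class, "prioritree_input_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_schema <- function(msg, ...) {
  stop(structure(
    class = c("prioritree_schema_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_feasibility <- function(msg, ...) {
  abort_input(msg, ..., class = "prioritree_feasibility_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
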