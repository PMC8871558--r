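# Classed error conditions used across the package. Every user-facing failure
# mode carries a condition class so callers (and tests) can dispatch on it.

csiStop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "csiError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

csiWarn <- function(class, msg) {
  warning(structure(
    class = c(class, "csiWarning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Amino-acid alphabet accepted in alignments: the 20 standard residues, the
# ambiguity code X, and the gap character.
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ALN_ALPHABET <- c(AA_LETTERS, "X", "-")

# seq() that returns integer(0) for empty ranges instead of counting down
seqRange <- function(from, to) {
  if (from > to) integer(0) else seq.int(from, to)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
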