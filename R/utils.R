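# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Raise a classed error so callers can distinguish validation failures.
pf_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "phepart_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

pf_check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) {
    pf_stop("phepart_nonnumeric_value", sprintf("'%s' must be numeric", name))
  }
  if (finite && any(!is.finite(x))) {
    pf_stop("phepart_nonnumeric_value",
            sprintf("'%s' contains non-finite values", name))
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed when one is given, restoring the
# caller's RNG state afterwards; with seed = NULL the ambient stream is used.
pf_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
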