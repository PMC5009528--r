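# internal helpers shared across modules

# normalize an unordered gene pair so the lexicographically smaller symbol
# comes first; vectorized over pairs
normalize_pairs <- function(a, b) {
  swap <- a > b
  tibble(
    gene_a = ifelse(swap, b, a),
    gene_b = ifelse(swap, a, b)
  )
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# sniff a delimiter among tab / comma / whitespace from the first data line
sniff_delim <- function(line) {
  if (grepl("\t", line)) return("\t")
  if (grepl(",", line)) return(",")
  "[[:space:]]+"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).",
      name,
      if (lower_open) "(" else "[", format(lower),
      format(upper), if (upper_open) ")" else "]",
      x
    ))
  }
  invisible(x)
}
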