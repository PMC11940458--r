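# Internal helpers shared across modules.

# Round half away from zero (2.5 -> 3, -2.5 -> -3). Likert responses are
# integer scale points; base round() uses banker's rounding, which would make
# the discretisation of latent means depend on parity.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

# Sample that never interprets a length-1 x as 1:x.
sample_safe <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}

assert_df <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
}

assert_cols <- function(x, cols, arg) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      arg, paste(missing, collapse = ", ")
    ))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
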