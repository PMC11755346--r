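# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a stage seed from a global seed; kept below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% 2147483587)
}

# Reorder the columns of `mat` to `expected` by name. Refuses silently
# mismatched feature spaces: predicting through a fitted schema must never
# depend on incidental column order.
align_columns <- function(mat, expected, what = "feature") {
  have <- colnames(mat)
  if (is.null(have)) {
    abort(sprintf("%s matrix must carry column names for schema alignment", what))
  }
  missing <- setdiff(expected, have)
  extra <- setdiff(have, expected)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(c(
      sprintf("%s columns do not match the model schema", what),
      "x" = if (length(missing)) paste0("missing: ", paste(utils::head(missing, 5), collapse = ", "),
                                        if (length(missing) > 5) ", ..."),
      "x" = if (length(extra)) paste0("unknown: ", paste(utils::head(extra, 5), collapse = ", "),
                                      if (length(extra) > 5) ", ...")
    ))
  }
  mat[, expected, drop = FALSE]
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s", name, format(min)))
  }
  invisible(x)
}
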