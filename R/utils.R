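# Internal helpers shared across modules.

# Stop with a consistent error class.
up_abort <- function(msg, class = "unitigphaser_error") {
  rlang::abort(msg, class = class)
}

# Check that a data frame has the given columns.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    up_abort(sprintf(
      "%s must have columns %s; missing: %s",
      what, paste(cols, collapse = ", "), paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Row-normalize a matrix; all-zero rows are left as zero.
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  keep <- n > 0
  m[keep, ] <- m[keep, , drop = FALSE] / n[keep]
  m
}

# Deterministic integer formatting for file output.
fmt_int <- function(x) formatC(round(x), format = "d")
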