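# Internal helpers shared across modules.

# Derive a reproducible child seed from a top-level seed and a stage tag.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "synovitcr_format_error")
  }
  invisible(df)
}

# Collapse a character vector into a canonical sorted key.
canonical_key <- function(x, sep = "+") {
  paste(sort(x), collapse = sep)
}
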