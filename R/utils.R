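# Small argument validators shared across the package.

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  }
  as.numeric(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop("'", name, "' must be an integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

assert_positive_scalar <- function(x, name) {
  x <- assert_finite_scalar(x, name)
  if (x <= 0) stop("'", name, "' must be > 0", call. = FALSE)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
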