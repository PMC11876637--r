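# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar checks; all error with the argument name so failures are traceable
check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %s", name, lower)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %s", name, lower)
  if (x > upper)
    stopf("`%s` must be <= %s", name, upper)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_num(x, name, lower = lower)
  if (x != as.integer(x)) stopf("`%s` must be an integer", name)
  as.integer(x)
}

# run `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# dense numeric matrix from anything matrix-like
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}
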