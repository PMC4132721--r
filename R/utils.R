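# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (no hidden global state; all randomness in
# the package flows from seeds passed explicitly).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be coercible to an integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a user seed, kept inside 32-bit range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483587L
}

tr_log <- function(fmt, ...) {
  message(sprintf(paste0("[trnaip] ", fmt), ...))
}

# Polynomial rolling hash of a character scalar, as an 8-hex-digit string.
# Used only to stamp dataset metadata with a fingerprint of the generating
# spec; not cryptographic.
spec_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483648))
}

# Recursively drop S3 classes so nested spec objects serialize as plain
# JSON (data frames become column lists; order is preserved, so the hash
# is stable).
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
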