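# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 32-bit-safe integer hash of an integer vector (polynomial
# rolling hash mod 2^31 - 1). Arithmetic stays below 2^53 so doubles are
# exact. Used for circular substructure identifiers and fingerprint folding.
.hash_ints <- function(v) {
  h <- 17
  for (x in v) {
    h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  }
  h
}

# string digest for config/artifact fingerprints (not cryptographic)
.hash_string <- function(s) {
  sprintf("%08x", .hash_ints(utf8ToInt(paste(s, collapse = "\x1f"))))
}

# derive a stage seed from a master seed; kept below 2^31
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 10007) %% 2147483629)
}

# stop unless all entries finite
.check_finite <- function(X, what = "feature matrix") {
  if (!all(is.finite(X))) {
    stop("validation error: non-finite values in ", what, call. = FALSE)
  }
  invisible(TRUE)
}
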