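# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}

assert_scalar_number <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("%s must be a single finite number", what)
  if (positive && x <= 0) stopf("%s must be > 0", what)
  invisible(x)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so seeded helpers do not perturb the session stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed in [0, 2^31 - 2]; keeps all derived seeds
# inside the 32-bit range set.seed() accepts.
derive_seed <- function(seed, index) {
  s <- (seed %% 2147483647) * 48271 + index * 1013904223
  as.integer(s %% 2147483647)
}

# Full-precision decimal rendering that round-trips doubles exactly.
format_full <- function(x) sprintf("%.17g", x)

# FNV-1a hash of a character scalar, hex string; used to fingerprint
# effective configs in reports (no cryptographic intent).
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
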