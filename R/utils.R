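# Shared internal helpers: constants, argument checks, seed handling, hashing.

# Vacuum permeability (SI, H/m).
MU0 <- 4e-7 * pi

stop_domain <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_domain(sprintf("'%s' must be a single non-missing number", name))
  if (finite && !is.finite(x))
    stop_domain(sprintf("'%s' must be finite", name))
  if (positive && x <= 0)
    stop_domain(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonnegative && x < 0)
    stop_domain(sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}

check_fraction <- function(x, name) {
  check_number(x, name, nonnegative = TRUE)
  if (x > 1)
    stop_domain(sprintf(
      "'%s' must be a fraction in [0, 1] (got %g); percent values belong in I/O only",
      name, x))
  invisible(x)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Small polynomial string hash (31-adic, mod 2^31 - 1); a provenance
# fingerprint for config blocks, not a cryptographic digest.
poly_hash <- function(s) {
  bytes <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
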