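# Internal helpers: seeded evaluation, counter-based child seeds, data hashes.

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Counter-based derivation of per-replicate / per-scenario seeds from a
# master seed, so re-running one scenario never shifts another.  Returns an
# integer in [1, 2^31 - 2].
childSeed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master %% 2147483647L)
  for (k in idx) {
    # Lehmer-style multiplicative mix; 48271 is a classic MINSTD multiplier
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

# md5 of a serialized object (used to guard model comparability).
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
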