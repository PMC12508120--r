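# Internal helpers: seeded evaluation and deterministic sub-stream derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All exported stochastic functions route
# their randomness through this so that a call is a pure function of its
# arguments plus the seed.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from (seed, k). Linear-congruential mixing in double
# precision; result always in [1, 2^31 - 2] so it is a valid set.seed() input.
mix_seed <- function(seed, k) {
  s <- abs(as.numeric(seed)) %% 2147483647
  k <- abs(as.numeric(k)) %% 2147483647
  as.integer(((s * 48271 + k * 16807 + 12345) %% 2147483629) + 1)
}

# Log-normal draw truncated at `upper` (rejection with a hard cap so the
# loop always terminates; the cap is effectively never reached under
# default latency parameters).
rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (i in which(x > upper)) {
    for (try in 1:50) {
      x[i] <- stats::rlnorm(1, meanlog, sdlog)
      if (x[i] <= upper) break
    }
    if (x[i] > upper) x[i] <- upper * 0.99
  }
  x
}

# FNV-1a hash of a character scalar, hex string. Used to stamp output files
# with a configuration fingerprint.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_prl <- function(msg, class) {
  stop(structure(class = c(class, "prl_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
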