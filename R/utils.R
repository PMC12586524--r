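# Small internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stable 31-bit FNV-style hash of a character string; used to derive
# reproducible sub-seeds from string identifiers and to seed the stub
# label-embedding provider. Independent of R's RNG state.
stable_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- xor_bits(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

xor_bits <- function(a, b) {
  bitwXor(as.integer(a %% 2147483647), as.integer(b))
}

# Derive a child seed below 2^31 from a base seed plus mixed components
# (integers or strings). Deterministic, order-sensitive.
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed %% 2147483647)
  for (p in parts) {
    v <- if (is.character(p)) stable_hash(p) else as.integer(p)
    h <- (h * 69069 + as.double(v) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

fg_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}
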