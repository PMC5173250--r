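# Internal helpers: seed derivation, scoped RNG, logging.

# 32-bit FNV-1a hash of a string, kept in [0, 2^31).
hash_string <- function(s) {
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2147483647)
}

# Deterministic child seed from a master seed and a string tag, so results
# do not depend on the order in which (TF, modulator) pairs are visited.
derive_seed <- function(master, tag) {
  as.integer((as.numeric(master) + hash_string(tag)) %% 2147483647L)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

mindy_log <- function(...) {
  if (isTRUE(getOption("mindyr.verbose", FALSE))) message("[mindyr] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
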