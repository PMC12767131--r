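# Internal helpers shared across modules.

# Error with a stable condition class so callers/tests can match on
# "hdpact_invalid_argument" rather than message text.
hd_stop <- function(msg, class = "hdpact_invalid_argument", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) hd_stop(msg)
  invisible(TRUE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
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

# FNV-1a hash of a serialized R object, as a hex string. Used to stamp
# checkpoints with a configuration fingerprint.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep arithmetic in doubles mod 2^32
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit multiply by the FNV prime without exceeding double precision
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
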