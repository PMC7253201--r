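#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map2 imap
NULL

# run expr with a local RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    abort("`seed` must be a single finite number.")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme used everywhere the package needs several
#' independent random streams from one user-supplied seed: replicate seeds,
#' per-multiplier seeds, bootstrap replicate seeds. Keeps results reproducible
#' from a single integer. The derived seed is always in `[0, 2^31 - 1)`.
#'
#' @param master Master seed (single integer).
#' @param ... One or more nonnegative integer counters (multiplier index,
#'   replicate index, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(idx >= 0))
  m <- 2^31 - 1
  h <- as.numeric(master) %% m
  for (k in idx) {
    # multiplicative mixing; constants fit exact double arithmetic below 2^53
    h <- (h * 69069 + as.numeric(k) + 1) %% m
    h <- (h * 48271) %% m
  }
  as.integer(h)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# FNV-1a 32-bit over a UTF-8 string, returned as 8 hex chars.
# Used to stamp run outputs with a configuration fingerprint.
# 32-bit modular multiply done in 16-bit halves to stay inside exact doubles.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    h0 <- h %% 2^16
    h1 <- h %/% 2^16
    # xor only affects the low byte; do it on the low half
    h0 <- h0 - (h0 %% 256) + bitwXor(as.integer(h0 %% 256), b)
    h <- (((h1 * p) %% 2^16) * 2^16 + h0 * p) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

config_hash <- function(x) {
  fnv1a32(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE))
}
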