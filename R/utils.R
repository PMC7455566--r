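#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG temporarily seeded at `seed`, restoring the
#' previous RNG state afterwards. With `seed = NULL` the expression simply
#' uses the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a child seed from a base seed and a stream label
#'
#' Deterministic, keeps results within 32-bit integer range so the same
#' base seed always yields the same per-stage streams.
#' @keywords internal
#' @noRd
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- fnv1a32(paste0(seed, "/", label))
  as.integer(h %% 2147483647)
}

# 32-bit FNV-1a hash of a character scalar, returned as a double in [0, 2^32).
# Used for config fingerprints in reports and for seed stream derivation.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30 # keep in int range
    h <- (h * 16777619) %% 4294967296
  }
  h
}

#' Short fingerprint of a configuration object
#' @keywords internal
#' @noRd
config_hash <- function(cfg) {
  h <- fnv1a32(paste(deparse(cfg), collapse = ""))
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite numeric scalar in [%s, %s]", name, lower, upper)
  invisible(x)
}
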