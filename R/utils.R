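#' FNV-1a hash of a character string
#'
#' Small deterministic 32-bit hash used to derive per-stage seeds and to
#' stamp pipeline outputs with a configuration fingerprint. Implemented here
#' so the package has no dependency on a digest library.
#'
#' @param x a character scalar.
#' @return integer scalar in `[0, 2^31 - 1]`.
#' @export
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    # xor into the low byte (b < 256), kept exact in double arithmetic
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit modular multiply via a 16-bit split (all intermediates < 2^53)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

#' Derive a per-stage seed from a global seed
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + as.numeric(fnv1a_hash(stage))) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi))
  invisible(x)
}
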