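# Internal utilities: classed errors, seeded-RNG scoping, deterministic hashing.

stop_dti <- function(msg, class = "dti_error", ...) {
  stop(structure(
    class = c(class, "dti_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_usage <- function(msg) stop_dti(msg, class = "dti_usage_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed without disturbing the
#' caller's random-number stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Polynomial rolling hash over non-negative integers, modulo the Mersenne
# prime 2^31 - 1. Doubles are exact below 2^53 so (h * 65599 + x) stays exact
# for h < 2^31 and x < 2^16; larger x are folded first.
MOD31 <- 2147483647

poly_hash <- function(ints) {
  h <- 5381
  for (x in ints) {
    x <- as.numeric(x)
    if (x < 0) x <- -2 * x + 1
    while (x >= 65536) {
      h <- (h * 65599 + (x %% 65536)) %% MOD31
      x <- x %/% 65536
    }
    h <- (h * 65599 + x) %% MOD31
  }
  h
}

hash_string <- function(s) poly_hash(utf8ToInt(s))

#' Derive a reproducible sub-seed (< 2^31) from a master seed and a stream name.
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer(poly_hash(c(as.numeric(seed) %% MOD31, utf8ToInt(stream))) %% .Machine$integer.max)
}

#' Cheap content fingerprint of an arbitrary R object (used to tie an index to
#' the model that produced its vectors). Not cryptographic.
#' @noRd
object_checksum <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # fold bytes in chunks to keep the loop short
  v <- as.integer(raw)
  n <- length(v)
  pad <- (-n) %% 8
  if (pad) v <- c(v, rep(0L, pad))
  m <- matrix(v, nrow = 8)
  folded <- as.numeric(m[1, ]) + 256 * m[2, ] + 65536 * m[3, ] +
    16777215 * (m[4, ] + m[5, ] + m[6, ] + m[7, ] + m[8, ])
  h <- 5381
  for (x in folded) h <- (h * 65599 + (x %% MOD31)) %% MOD31
  sprintf("%d-%d", n, as.integer(h))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
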