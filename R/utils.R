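# Small shared helpers: seed scoping and a plain-text content hash.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded helpers do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Stable content hash of an R object
#'
#' Polynomial rolling hash (base 257 modulo the Mersenne prime 2^31 - 1)
#' over the object's deparsed representation; used to stamp artifacts
#' with the configuration that produced them. Not cryptographic.
#'
#' @param x any serializable R object.
#' @return an 8-hex-digit string.
#' @export
content_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  m <- 2147483647
  h <- 17
  for (b in bytes) {
    # both operands stay < 2^53 so double arithmetic is exact
    h <- (h * 257 + b + 1) %% m
  }
  sprintf("%08x", h)
}

#' Derive a bounded integer sub-seed from a base seed and a stream label
#'
#' Expands one user-facing seed into independent per-module streams by
#' hashing the label; results stay below 2^31 so they are valid R seeds.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  as.integer(strtoi(content_hash(lab), base = 16L) %% 2147483647)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
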