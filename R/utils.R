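# Deterministic seed substreams and local-RNG helpers shared across modules.

#' Derive a deterministic substream seed
#'
#' Hashes an integer master seed together with an arbitrary set of string /
#' numeric labels into a positive 32-bit integer.  Used so that every model,
#' condition and replicate draws from an independent, reproducible stream.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return a positive integer scalar strictly below 2^31.
#' @export
substreamSeed <- function(seed, ...) {
  parts <- vapply(list(...), function(x) paste(format(x, trim = TRUE),
                                               collapse = "|"), character(1))
  bytes <- utf8ToInt(paste(parts, collapse = "/"))
  h <- as.double(seed) %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(max(h, 1))
}

# Evaluate expr with the global RNG temporarily seeded; restores prior state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# paste a ternary integer vector into a stable profile key like "0,1,-1"
profileKey <- function(x) paste(as.integer(x), collapse = ",")
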