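# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a stream-specific RNG seed from a master seed; stays below 2^31 - 1
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 7919 + as.numeric(p) * 131 + 17) %% 2147483647
  as.integer(h)
}

# run expr with a local RNG state so simulators do not disturb the caller
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
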