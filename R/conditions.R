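# Structured error conditions used across the package.

stop_odesio <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("odesio_", class), "odesio_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Primes backing the two modular working fields
#'
#' Both engines perform all rank and power-series computations by exact
#' arithmetic in a prime field GF(p).  Two distinct primes just below 2^31
#' are available so that any classification can be cross-checked in an
#' independent field: an unlucky prime (one dividing a relevant minor) would
#' have to be unlucky in both fields simultaneously for an error to go
#' unnoticed.
#'
#' @param field `"modular"` (the default prime, 2^31 - 1) or `"modular2"`
#'   (an independent prime, 2147483629).
#' @return The prime as a double.
#' @export
sio_prime <- function(field = c("modular", "modular2")) {
  field <- match.arg(field)
  switch(field, modular = 2147483647, modular2 = 2147483629)
}

# Run code with a locally-seeded RNG without disturbing the caller's stream.
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

# Random nonzero field elements for specialization: uniform on [2, 2^20].
# The lower bound 2 keeps monomials that vanish at 0/1 (for instance every
# interaction term of a Lotka-Volterra model at the origin) away from
# trivially degenerate points.
draw_points <- function(k) {
  if (k == 0) return(integer(0))
  sample(1048575L, k) + 1L
}
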