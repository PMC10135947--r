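# Independent pure-R oracle for exact modular evaluation and rank.
#
# This deliberately shares no code with the package internals: expressions
# are evaluated by recursive walking of the R parse tree with %%-arithmetic
# over a small prime (products stay far below 2^53 in doubles), and ranks
# come from a plain R Gaussian elimination.  Used to freeze expected values
# for the engines' [DERIVED]-style examples.

ORACLE_P <- 99991

o_powmod <- function(a, e, p) {
  a <- a %% p
  r <- 1
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * a) %% p
    a <- (a * a) %% p
    e <- e %/% 2
  }
  r
}

o_inv <- function(a, p) o_powmod(a %% p, p - 2, p)

# Evaluate an R arithmetic expression mod p given named integer values.
o_eval <- function(e, values, p = ORACLE_P) {
  rec <- function(e) {
    if (is.numeric(e)) {
      v <- as.numeric(e)
      if (v == floor(v)) return(v %% p)
      stop("oracle: non-integer literal")
    }
    if (is.name(e)) {
      nm <- as.character(e)
      if (is.null(values[[nm]])) stop("oracle: missing value for ", nm)
      return(values[[nm]] %% p)
    }
    fn <- as.character(e[[1]])
    if (fn == "(") return(rec(e[[2]]))
    if (length(e) == 2) {
      if (fn == "-") return((p - rec(e[[2]])) %% p)
      if (fn == "+") return(rec(e[[2]]))
    }
    a <- rec(e[[2]])
    b <- if (fn == "^") as.numeric(e[[3]]) else rec(e[[3]])
    switch(fn,
           "+" = (a + b) %% p,
           "-" = (a - b) %% p,
           "*" = (a * b) %% p,
           "/" = { if (b == 0) stop("oracle: division by zero")
                   (a * o_inv(b, p)) %% p },
           "^" = { if (b < 0) o_powmod(o_inv(a, p), -b, p)
                   else o_powmod(a, b, p) },
           stop("oracle: unsupported operator ", fn))
  }
  rec(e)
}

# Plain Gaussian elimination rank over GF(p).
o_rank <- function(M, p = ORACLE_P) {
  M <- M %% p
  nr <- nrow(M); nc <- ncol(M)
  rank <- 0
  for (c in seq_len(nc)) {
    if (rank == nr) break
    piv <- which(M[(rank + 1):nr, c] != 0)
    if (length(piv) == 0) next
    piv <- piv[1] + rank
    if (piv != rank + 1) M[c(piv, rank + 1), ] <- M[c(rank + 1, piv), ]
    rank <- rank + 1
    ip <- o_inv(M[rank, c], p)
    if (rank < nr) {
      for (r in (rank + 1):nr) {
        f <- (M[r, c] * ip) %% p
        if (f != 0) M[r, ] <- (M[r, ] - f * M[rank, ]) %% p
      }
    }
  }
  rank
}

# Independent Lie-derivative path built on base D(): total derivative of
# h along the augmented field (autonomous models only -- sufficient for
# the oracle fixtures it is used on).
o_lie <- function(h, states, dynamics) {
  out <- quote(0)
  for (i in seq_along(states)) {
    dh <- D(h, states[i])
    out <- call("+", out, call("*", dh, dynamics[[i]]))
  }
  out
}

# Generic rank of the observability-identifiability matrix computed
# entirely through base D() + o_eval + o_rank.
o_oi_rank <- function(model, orders, seed = 99, n_points = 3) {
  aug_states <- c(model$states, model$parameters)
  aug_dyn <- c(model$dynamics, rep(list(quote(0)), length(model$parameters)))
  levels <- list(model$outputs)
  for (b in seq_len(orders))
    levels[[b + 1]] <- lapply(levels[[b]], o_lie, states = model$states,
                              dynamics = model$dynamics)
  rows <- list()
  for (lev in levels)
    for (h in lev)
      rows[[length(rows) + 1]] <- lapply(aug_states, function(s) D(h, s))
  set.seed(seed)
  best <- 0
  for (pt in seq_len(n_points)) {
    vals <- as.list(sample(2:1000, length(aug_states)))
    names(vals) <- aug_states
    M <- t(vapply(rows, function(r)
      vapply(r, o_eval, numeric(1), values = vals), numeric(length(aug_states))))
    best <- max(best, o_rank(M))
  }
  best
}
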