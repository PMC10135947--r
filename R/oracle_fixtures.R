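# Ground-truth oracles, independent of both engines.
#
# Two families: random linear systems, whose observability is settled by
# the Kalman rank condition (a purely linear-algebra computation sharing no
# code with the engines), and nonlinear fixtures constructed from an
# explicit symmetry, whose unidentifiable sets are known by construction.

oracle_primes <- c(2147483647, 2147483629)

# Exact rank of an integer matrix: maximum of the GF(p) ranks over two
# independent primes (rank mod p never exceeds the rational rank, and a
# deficiency would require both primes to divide the same minor).
int_rank_drop <- function(M) {
  res <- lapply(oracle_primes, function(p) cpp_mod_rank_drop(M, p))
  Reduce(pmax, res)
}

#' Kalman observability of a linear system
#'
#' For `x' = A x`, `y = C x`, stacks the observability matrix
#' `[C; CA; ...; CA^(n-1)]` and computes its exact rank; state i is
#' observable if and only if deleting column i lowers the rank.  This is
#' the classical linear special case of the rank criterion and serves as a
#' ground-truth oracle for both nonlinear engines.
#'
#' @param A n x n integer matrix.
#' @param C m x n integer matrix.
#' @return A list with `rank`, `observability_matrix` and `state_status`
#'   (named character vector, `"observable"` / `"unobservable"`).
#' @examples
#' kalman_observability(matrix(c(0, 0, 1, 0), 2), matrix(c(1, 0), 1))
#' @export
kalman_observability <- function(A, C) {
  A <- as.matrix(A); C <- as.matrix(C)
  n <- nrow(A)
  if (ncol(A) != n || ncol(C) != n)
    stop_odesio("dimension_mismatch",
                "A must be n x n and C must be m x n")
  O <- C
  Ck <- C
  for (k in seq_len(n - 1L)) {
    Ck <- Ck %*% A
    O <- rbind(O, Ck)
  }
  if (max(abs(O)) > 2^52) stop_odesio("invalid_expression",
                                      "observability matrix entries too large")
  drops <- int_rank_drop(O)
  rank <- drops[1]
  status <- ifelse(drops[-1] < rank, "observable", "unobservable")
  names(status) <- paste0("x", seq_len(n))
  list(rank = as.integer(rank), observability_matrix = O,
       state_status = status)
}

#' Random linear observability fixture
#'
#' Draws a sparse random system matrix with small integer entries and a
#' measurement matrix selecting m distinct states, attaches the Kalman
#' ground truth, and wraps the system as an `ode_model` (with no unknown
#' parameters) so that both nonlinear engines can be run on it.
#'
#' @param n State dimension (1..8; small integers in \[-3, 3\] keep exact
#'   ranks instant while exercising structure).
#' @param m Number of measured states (1..n).
#' @param seed Seed; the same seed reproduces the fixture exactly.
#' @param sparsity Probability that an entry of A is zeroed.
#' @return A list of class `linear_fixture` with `A`, `C`, `model` and
#'   `truth` (the [kalman_observability()] result).
#' @export
random_linear_fixture <- function(n, m, seed = 1L, sparsity = 0.5) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 1L || n > 8L || is.na(m) || m < 1L || m > n)
    stop_odesio("dimension_mismatch", "need 1 <= m <= n <= 8")
  with_seed(seed, {
    A <- matrix(sample(-3:3, n * n, replace = TRUE), n, n)
    A[matrix(stats::runif(n * n) < sparsity, n, n)] <- 0L
    sel <- sort(sample.int(n, m))
    C <- diag(n)[sel, , drop = FALSE]
    truth <- kalman_observability(A, C)
    states <- paste0("x", seq_len(n))
    dyn <- vapply(seq_len(n), function(i) {
      terms <- vapply(which(A[i, ] != 0), function(j)
        sprintf("(%d)*x%d", A[i, j], j), "")
      if (length(terms) == 0) "0" else paste(terms, collapse = " + ")
    }, "")
    model <- ode_model(states = states, dynamics = dyn,
                       outputs = states[sel],
                       name = sprintf("linear_n%d_m%d_s%d", n, m, seed))
    structure(list(A = A, C = C, sel = sel, model = model, truth = truth,
                   seed = seed),
              class = "linear_fixture")
  })
}

#' @export
print.linear_fixture <- function(x, ...) {
  cat(sprintf("Linear fixture (n = %d, measuring %s): Kalman rank %d\n",
              nrow(x$A), paste0("x", x$sel, collapse = ","), x$truth$rank))
  invisible(x)
}

#' Symmetry-constructed nonlinear fixtures
#'
#' Models whose structurally unidentifiable parameters are certified by an
#' explicit symmetry transformation rather than by either engine:
#' \describe{
#'   \item{`"product"`}{`x' = th1 th2 x`, `y = x`: only the product
#'     `th1 th2` enters the dynamics, so the scaling `th1 -> c th1`,
#'     `th2 -> th2 / c` fixes the output and both parameters are SU while
#'     `x` stays observable.}
#'   \item{`"state_scaling"`}{the 2-species gLV model measured through
#'     `x1` only: `x2 -> c x2`, `b12 -> b12 / c`, `b22 -> b22 / c` fixes
#'     the output, certifying SU of `{b12, b22}` and unobservability of
#'     `x2`.}
#' }
#'
#' @param kind `"product"` or `"state_scaling"`.
#' @return A list with `model`, the certified `su` parameter set, the
#'   certified `unobservable` state set, and `transform(values, c)`
#'   applying the symmetry to a specialization point.
#' @export
symmetry_fixture <- function(kind = c("product", "state_scaling")) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("product", "state_scaling"))
    stop_odesio("unknown_kind", "unknown symmetry fixture kind")
  if (kind == "product") {
    model <- ode_model(states = "x", parameters = c("th1", "th2"),
                       dynamics = "th1*th2*x", outputs = "x",
                       name = "sym_product")
    transform <- function(values, c) {
      values[["th1"]] <- values[["th1"]] * c
      values[["th2"]] <- values[["th2"]] / c
      values
    }
    return(list(model = model, su = c("th1", "th2"),
                unobservable = character(), transform = transform))
  }
  model <- with_outputs(glv_model(2), output_config("x1", "x1"))
  model$name <- "sym_state_scaling"
  transform <- function(values, c) {
    values[["x2"]] <- values[["x2"]] * c
    values[["b12"]] <- values[["b12"]] / c
    values[["b22"]] <- values[["b22"]] / c
    values
  }
  list(model = model, su = c("b12", "b22"), unobservable = "x2",
       transform = transform)
}
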