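# Probabilistic algebraic engine
#
# Local algebraic observability is tested in probabilistic polynomial time:
# the parameters, initial conditions and inputs of the augmented system are
# specialized at random elements of the working field, the augmented ODE
# and its variational system X' = (df~/dx~) X, X(0) = I are solved as
# truncated power series in t, and the Jacobian of the output series
# coefficients with respect to the augmented initial conditions,
#   rows = coefficients of orders 0..(n+p) of (dh/dx~)(x~(t)) X(t),
# is ranked exactly in GF(p).  The transcendence degree of the output field
# extension equals (n+p) - rank; degree zero means the model is
# algebraically observable (FISPO).  Non-observable components are located
# by the same column-removal rule as the Lie engine, which makes the two
# engines directly comparable.

#' Variational (sensitivity) system of an augmented model
#'
#' Builds the symbolic Jacobian of the augmented dynamics with respect to
#' the augmented state.  Parameter rows are identically zero; input symbols
#' are left free for later specialization.
#'
#' @param model An `ode_model` or `aug_model`.
#' @return An object of class `variational_system` with the Jacobian as a
#'   matrix of R expressions (element `jacobian`).
#' @export
variational_system <- function(model) {
  aug <- augment(model)
  np <- length(aug$aug_states)
  ec <- engine_ctx(aug)
  jac_ids <- matrix(0L, np, np)
  for (i in seq_len(np))
    for (j in seq_len(np))
      jac_ids[i, j] <- cpp_dag_diff(ec$ptr, ec$f_ids[i], j)
  jac <- matrix(list(), np, np,
                dimnames = list(aug$aug_states, aug$aug_states))
  for (i in seq_len(np))
    for (j in seq_len(np))
      jac[[i, j]] <- dag_to_expr(ec$ptr, jac_ids[i, j])
  structure(list(aug = aug, jacobian = jac), class = "variational_system")
}

#' @export
print.variational_system <- function(x, ...) {
  np <- length(x$aug$aug_states)
  cat(sprintf("Variational system of '%s': %d x %d Jacobian (parameter rows zero)\n",
              x$aug$base$name, np, np))
  invisible(x)
}

# Build the time-substituted DAG used by the series computations: inputs
# are replaced by explicit polynomials in t with the given coefficients.
series_ctx <- function(aug, input_polys) {
  model <- aug$base
  ptr <- dag_new(c(aug$aug_states, "t"))
  subs <- model$known_constants
  tname <- as.name("t")
  for (u in names(input_polys)) {
    cf <- input_polys[[u]]
    poly <- NULL
    for (k in seq_along(cf)) {
      term <- if (k == 1) cf[k] else call("*", cf[k], call("^", tname, k - 1L))
      poly <- if (is.null(poly)) term else call("+", poly, term)
    }
    subs[[u]] <- poly
  }
  np <- length(aug$aug_states)
  f_ids <- vapply(aug$aug_dynamics, function(e)
    dag_from_expr(ptr, subst_symbols(e, subs)), integer(1))
  h_ids <- vapply(model$outputs, function(e)
    dag_from_expr(ptr, subst_symbols(e, subs)), integer(1))
  n <- length(model$states)
  jac_ids <- matrix(0L, n, np)        # parameter rows vanish; skip them
  for (i in seq_len(n))
    for (j in seq_len(np))
      jac_ids[i, j] <- cpp_dag_diff(ptr, f_ids[i], j)
  H_ids <- matrix(0L, length(h_ids), np)
  for (o in seq_along(h_ids))
    for (j in seq_len(np))
      H_ids[o, j] <- cpp_dag_diff(ptr, h_ids[o], j)
  list(ptr = ptr, f_ids = f_ids, h_ids = h_ids, jac_ids = jac_ids,
       H_ids = H_ids, np = np, n = n, t_var = np + 1L)
}

#' Specialize a variational system at random field elements
#'
#' Parameters and initial conditions are replaced by independent random
#' integers in \[2, 2^20\]; each input is replaced by a random polynomial
#' in t whose degree is the input's nonzero-derivative count (a generic
#' smooth input uses degree n + p).
#'
#' @param vs A `variational_system`.
#' @param seed Seed for the draws.
#' @param field Working field, see [sio_prime()].
#' @return An object of class `specialized_system` recording the draws.
#' @export
specialize <- function(vs, seed = 1L, field = "modular") {
  stopifnot(inherits(vs, "variational_system"))
  aug <- vs$aug
  model <- aug$base
  np <- length(aug$aug_states)
  prime <- sio_prime(field)
  with_seed(seed, {
    x0 <- stats::setNames(draw_points(np), aug$aug_states)
    input_polys <- list()
    for (u in model$inputs) {
      d <- model$input_derivatives[[u]]
      if (is.na(d)) d <- np                    # generic smooth input
      input_polys[[u]] <- draw_points(d + 1L)
    }
    sc <- series_ctx(aug, input_polys)
    structure(
      list(aug = aug, sc = sc, x0 = x0, input_polys = input_polys,
           prime = prime, seed = seed),
      class = "specialized_system")
  })
}

#' @export
print.specialized_system <- function(x, ...) {
  cat(sprintf("Specialized system of '%s' over GF(%d), seed %d\n",
              x$aug$base$name, x$prime, x$seed))
  invisible(x)
}

#' Truncated power-series solution of a specialized system
#'
#' Solves the specialized augmented ODE and its variational system as
#' power series in t.  The series coefficients satisfy the ODE recurrence
#' exactly (this is asserted on every solve); the sensitivity series
#' starts at the identity.
#'
#' @param ss A `specialized_system`.
#' @param order Truncation order; the default `(n + p) + 1` retains one
#'   coefficient more than the output Jacobian needs.
#' @return An object of class `series_solution` with elements
#'   `truncation_order`, `state_series` ((n+p) x (order+1) matrix of field
#'   elements) and `sensitivity_series`.
#' @export
series_solve <- function(ss, order = NULL) {
  stopifnot(inherits(ss, "specialized_system"))
  np <- ss$sc$np
  order <- as.integer(order %||% (np + 1L))
  if (order < 1L) stop_odesio("order_negative", "order must be >= 1")
  L <- order + 1L
  f_nodes <- ss$sc$f_ids
  # identically-zero parameter dynamics are encoded as node id 0
  f_nodes[vapply(f_nodes, function(id) dag_is_zero(ss$sc$ptr, id),
                 logical(1))] <- 0L
  sol <- cpp_dag_series_ode(ss$sc$ptr, as.integer(f_nodes),
                            as.numeric(ss$x0), ss$sc$t_var, L, ss$prime)
  if (!sol$ok)
    stop_odesio("field_division",
                "specialization hit a pole of the dynamics; re-specialize")
  if (!isTRUE(sol$resid_ok))
    stop("internal error: series solution violates the ODE recurrence")
  xser <- sol$xser
  rownames(xser) <- ss$aug$aug_states

  varser <- rbind(xser, t = c(0, 1, rep(0, L - 2L)))
  jres <- cpp_dag_eval_series(ss$sc$ptr, as.integer(ss$sc$jac_ids), varser,
                              ss$prime)
  if (!jres$ok)
    stop_odesio("field_division",
                "specialization hit a pole of the Jacobian; re-specialize")
  # rows of jres$values follow column-major order of jac_ids; reorder to
  # (i-1)*np + j row layout expected by the sensitivity recursion
  n <- ss$sc$n
  Jser <- matrix(0, n * np, L)
  for (i in seq_len(n))
    for (j in seq_len(np))
      Jser[(i - 1L) * np + j, ] <- jres$values[(j - 1L) * n + i, ]
  Xser <- cpp_sens_series(Jser, n, np, ss$prime)

  structure(
    list(truncation_order = order, state_series = xser,
         sensitivity_series = Xser, var_series = varser, ss = ss,
         prime = ss$prime),
    class = "series_solution")
}

#' @export
print.series_solution <- function(x, ...) {
  cat(sprintf("Power-series solution over GF(%d), truncation order %d\n",
              x$prime, x$truncation_order))
  invisible(x)
}

#' Coefficient Jacobian of the outputs
#'
#' Evaluates the output Jacobian dh/dx~ along the series solution,
#' multiplies by the sensitivity series X(t), and stacks the coefficients
#' of orders 0..(n+p): row block k holds the t^k coefficient of
#' dy/dx~(0).  Columns are labelled by the augmented components.
#'
#' @param ss A `specialized_system`.
#' @param series The matching `series_solution` (order at least n + p).
#' @return A numeric matrix of field elements with attribute `prime`.
#' @export
output_jacobian <- function(ss, series) {
  stopifnot(inherits(ss, "specialized_system"),
            inherits(series, "series_solution"))
  np <- ss$sc$np
  if (series$truncation_order < np)
    stop_odesio("order_negative",
                "series order %d is below n + p = %d",
                series$truncation_order, np)
  m <- length(ss$sc$h_ids)
  hres <- cpp_dag_eval_series(ss$sc$ptr, as.integer(t(ss$sc$H_ids)),
                              series$var_series, ss$prime)
  if (!hres$ok)
    stop_odesio("field_division",
                "specialization hit a pole of the output Jacobian")
  # rows of hres follow t(H_ids): output-major blocks of np rows
  jac <- cpp_stack_jac(hres$values, series$sensitivity_series, m, np,
                       np + 1L, ss$prime)
  colnames(jac) <- ss$aug$aug_states
  attr(jac, "prime") <- ss$prime
  jac
}

#' Transcendence degree of the output field extension
#'
#' For a coefficient Jacobian from [output_jacobian()], the transcendence
#' degree equals (n + p) minus the matrix rank; zero certifies local
#' algebraic observability (FISPO).
#'
#' @param jac Matrix from [output_jacobian()] (attribute `prime` set), or
#'   any numeric matrix plus an explicit `prime`.
#' @param prime Field prime; defaults to the matrix attribute.
#' @return Integer transcendence degree.
#' @export
transcendence_degree <- function(jac, prime = attr(jac, "prime")) {
  if (is.null(prime)) stop_odesio("invalid_expression", "prime not given")
  ncol(jac) - cpp_mod_rank(jac, prime)
}

#' Classify a model with the probabilistic algebraic engine
#'
#' Runs the full specialization / power-series / coefficient-Jacobian
#' pipeline `trials` times with independent draws and classifies every
#' augmented component by the column-removal rule on the coefficient
#' Jacobian, taking the maximum rank over trials.  Specializations hitting
#' a pole of the rational dynamics are redrawn (up to five attempts each).
#'
#' @inheritParams sio_lie
#' @return An object of class `sio_result` with engine tag `"algebraic"`.
#' @export
sio_algebraic <- function(model, config = NULL, seed = 1L, trials = 2L,
                          field = "modular") {
  if (!is.null(config)) model <- with_outputs(model, config)
  vs <- variational_system(model)
  np <- length(vs$aug$aug_states)
  prime <- sio_prime(field)
  with_seed(seed, {
    sub_seeds <- sample.int(2147483646L, trials + 5L)
    drops <- list()
    draws <- list()
    t <- 1L
    attempt <- 1L
    while (t <= trials) {
      if (attempt > length(sub_seeds))
        stop_odesio("degenerate", "all specializations hit a singular locus")
      ssd <- sub_seeds[attempt]
      attempt <- attempt + 1L
      ok <- tryCatch({
        ss <- specialize(vs, seed = ssd, field = field)
        sol <- series_solve(ss)
        jac <- output_jacobian(ss, sol)
        drops[[t]] <- cpp_mod_rank_drop(jac, prime)
        draws[[t]] <- list(x0 = ss$x0, inputs = ss$input_polys, seed = ssd)
        TRUE
      }, odesio_field_division = function(c) FALSE)
      if (ok) t <- t + 1L
    }
    full <- max(vapply(drops, `[`, integer(1), 1L))
    col_ranks <- apply(do.call(rbind, lapply(drops, function(d) d[-1])), 2,
                       max)
    names(col_ranks) <- vs$aug$aug_states
    new_sio_result(
      model = model, engine = "algebraic", seed = seed, rank = full,
      col_ranks = col_ranks, prime = prime,
      evidence = list(trials = trials, draws = draws,
                      transcendence_degree = np - full))
  })
}

#' Output power series at a chosen specialization
#'
#' Solves the model forward as a truncated power series from
#' user-supplied integer values for states, parameters and input
#' polynomial coefficients, and returns the series coefficients of each
#' output.  This is the quantity preserved by a structural symmetry: a
#' transformation of states and parameters that certifies unidentifiability
#' leaves these coefficients unchanged.
#'
#' @param model An `ode_model`.
#' @param values Named list/vector of integer values for every state and
#'   parameter; inputs (if any) map to integer coefficient vectors of their
#'   specialization polynomial.
#' @param order Truncation order (default n + p + 1).
#' @param field Working field, see [sio_prime()].
#' @return An m x (order + 1) matrix of field elements, outputs in rows.
#' @export
sio_output_series <- function(model, values, order = NULL,
                              field = "modular") {
  stopifnot(inherits(model, "ode_model"))
  aug <- augment(model)
  np <- length(aug$aug_states)
  order <- as.integer(order %||% (np + 1L))
  prime <- sio_prime(field)
  values <- as.list(values)
  missing <- setdiff(aug$aug_states, names(values))
  if (length(missing) > 0)
    stop_odesio("invalid_expression", "missing values for: %s",
                paste(missing, collapse = ", "))
  input_polys <- list()
  for (u in model$inputs) {
    if (is.null(values[[u]]))
      stop_odesio("invalid_expression", "missing input coefficients for '%s'", u)
    input_polys[[u]] <- as.numeric(values[[u]])
  }
  sc <- series_ctx(aug, input_polys)
  L <- order + 1L
  f_nodes <- sc$f_ids
  f_nodes[vapply(f_nodes, function(id) dag_is_zero(sc$ptr, id),
                 logical(1))] <- 0L
  x0 <- vapply(aug$aug_states, function(s) as.numeric(values[[s]]),
               numeric(1))
  if (any(x0 != floor(x0)) ||
      any(vapply(input_polys, function(cf) any(cf != floor(cf)), logical(1))))
    stop_odesio("invalid_expression",
                "specialization values must be integers (field elements)")
  sol <- cpp_dag_series_ode(sc$ptr, as.integer(f_nodes), x0, sc$t_var, L,
                            prime)
  if (!sol$ok)
    stop_odesio("field_division", "chosen values hit a pole of the dynamics")
  varser <- rbind(sol$xser, t = c(0, 1, rep(0, L - 2L)))
  hres <- cpp_dag_eval_series(sc$ptr, as.integer(sc$h_ids), varser, prime)
  if (!hres$ok)
    stop_odesio("field_division", "chosen values hit a pole of the outputs")
  out <- hres$values
  rownames(out) <- paste0("y", seq_len(nrow(out)))
  attr(out, "prime") <- prime
  out
}
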