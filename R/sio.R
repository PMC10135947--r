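# Front door and the sio_result class shared by both engines.

new_sio_result <- function(model, engine, seed, rank, col_ranks, prime,
                           evidence = list()) {
  np <- length(model$states) + length(model$parameters)
  fispo <- rank == np
  determinable <- col_ranks < rank
  par_status <- stats::setNames(
    c("SU", "SLI")[determinable[model$parameters] + 1L], model$parameters)
  st_status <- stats::setNames(
    c("unobservable", "observable")[determinable[model$states] + 1L],
    model$states)
  structure(
    list(model_name = model$name,
         config_label = model$config_label %||%
           paste(vapply(model$outputs, deparse1, ""), collapse = ","),
         engine = engine, seed = seed, rank = as.integer(rank),
         full_dim = as.integer(np), fispo = fispo,
         parameter_status = par_status, state_status = st_status,
         prime = prime,
         evidence = c(list(column_ranks = col_ranks), evidence)),
    class = "sio_result")
}

sli_set <- function(res) names(res$parameter_status[res$parameter_status == "SLI"])
su_set <- function(res) names(res$parameter_status[res$parameter_status == "SU"])
obs_set <- function(res) names(res$state_status[res$state_status == "observable"])
unobs_set <- function(res) names(res$state_status[res$state_status == "unobservable"])

#' Structural identifiability and observability analysis
#'
#' Determines, from the model equations alone, which parameters of a
#' nonlinear ODE model are structurally locally identifiable (SLI) and
#' which states are observable from the chosen measurements, and whether
#' the model enjoys full input, state and parameter observability (FISPO).
#'
#' Two independent engines are available. `"lie"` builds the
#' observability-identifiability matrix from Lie derivatives of the outputs
#' and computes its generic rank ([sio_lie()]).  `"algebraic"` (the
#' default, and much faster on large models) runs a probabilistic
#' polynomial-time test: it specializes parameters, initial conditions and
#' inputs at random field elements, solves the variational system as a
#' truncated power series, and ranks the Jacobian of the output series
#' coefficients ([sio_algebraic()]).  `"both"` runs the two and records
#' whether they agree.
#'
#' @param model An `ode_model`, e.g. from [ode_model()] or the model zoo
#'   ([glv_model()], [clv_model()], [qsmi_model()], [msmi_model()],
#'   [pc_model()]).
#' @param outputs Optional measurement configuration ([output_config()] or
#'   character vector of expressions over the states); defaults to the
#'   model's own outputs.
#' @param engine `"algebraic"`, `"lie"` or `"both"`.
#' @param seed Integer seed driving every random specialization.
#' @param trials Number of independent specializations per rank (the
#'   maximum of the observed exact ranks is used).
#' @param field Working field, see [sio_prime()].
#' @param ... Passed to the engine ([sio_lie()] or [sio_algebraic()]).
#' @return An object of class `sio_result` (for `engine = "both"`, class
#'   `sio_result_pair` with elements `lie`, `algebraic` and `agree`).
#' @examples
#' res <- sio(glv_model(2), outputs = "x1", seed = 7)
#' print(res)
#' @export
sio <- function(model, outputs = NULL, engine = c("algebraic", "lie", "both"),
                seed = 1L, trials = 2L, field = "modular", ...) {
  engine <- match.arg(engine)
  if (is.character(outputs) && !inherits(outputs, "output_config"))
    outputs <- output_config(paste(outputs, collapse = ","), outputs)
  if (engine == "both") {
    lie <- sio_lie(model, config = outputs, seed = seed, trials = trials,
                   field = field, ...)
    alg <- sio_algebraic(model, config = outputs, seed = seed,
                         trials = trials, field = field, ...)
    return(structure(list(lie = lie, algebraic = alg,
                          agree = results_agree(lie, alg)),
                     class = "sio_result_pair"))
  }
  fn <- switch(engine, lie = sio_lie, algebraic = sio_algebraic)
  fn(model, config = outputs, seed = seed, trials = trials, field = field,
     ...)
}

#' Do two analyses agree?
#'
#' Compares rank, FISPO flag and the per-parameter / per-state
#' classifications of two `sio_result`s (engine tag and evidence are
#' ignored).
#'
#' @param a,b `sio_result` objects for the same model and configuration.
#' @return `TRUE` or `FALSE`.
#' @export
results_agree <- function(a, b) {
  identical(a$rank, b$rank) && identical(a$fispo, b$fispo) &&
    identical(a$parameter_status, b$parameter_status) &&
    identical(a$state_status, b$state_status)
}

fmt_set <- function(x) if (length(x) == 0) "-" else paste(x, collapse = ", ")

#' @export
print.sio_result <- function(x, ...) {
  cat(sprintf("SIO analysis of '%s' (outputs: %s) [engine: %s, seed %d]\n",
              x$model_name, x$config_label, x$engine, x$seed))
  cat(sprintf("  rank %d of %d -> %s\n", x$rank, x$full_dim,
              if (x$fispo) "FISPO (all parameters SLI, all states observable)"
              else "not FISPO"))
  cat("  identifiable (SLI):   ", fmt_set(sli_set(x)), "\n")
  cat("  unidentifiable (SU):  ", fmt_set(su_set(x)), "\n")
  cat("  observable states:    ", fmt_set(obs_set(x)), "\n")
  cat("  unobservable states:  ", fmt_set(unobs_set(x)), "\n")
  invisible(x)
}

#' @export
summary.sio_result <- function(object, ...) {
  out <- list(
    model = object$model_name, config = object$config_label,
    engine = object$engine, rank = object$rank, full_dim = object$full_dim,
    fispo = object$fispo,
    n_sli = sum(object$parameter_status == "SLI"),
    n_su = sum(object$parameter_status == "SU"),
    n_observable = sum(object$state_status == "observable"),
    n_unobservable = sum(object$state_status == "unobservable"))
  class(out) <- "summary.sio_result"
  out
}

#' @export
print.summary.sio_result <- function(x, ...) {
  cat(sprintf("%s | %s | rank %d/%d | %s | SLI %d, SU %d | obs %d, unobs %d\n",
              x$model, x$config, x$rank, x$full_dim,
              if (x$fispo) "FISPO" else "not FISPO",
              x$n_sli, x$n_su, x$n_observable, x$n_unobservable))
  invisible(x)
}

#' @export
print.sio_result_pair <- function(x, ...) {
  print(x$lie)
  print(x$algebraic)
  cat(sprintf("Engines agree: %s\n", x$agree))
  invisible(x)
}
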