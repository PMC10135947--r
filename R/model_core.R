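# Symbolic ODE models
#
# A model is
#     x'(t) = f(x(t), u(t), theta),   y(t) = h(x(t), u(t), theta)
# with states x (dimension n), unknown parameters theta (dimension p),
# known inputs u (dimension q) and outputs y (dimension m).  Dynamics and
# outputs must be rational functions of their symbols, which covers every
# microbial community model family shipped in the zoo.

normalize_exprs <- function(x, what) {
  if (is.null(x)) return(list())
  if (is.character(x)) {
    x <- lapply(x, function(s) {
      tryCatch(str2lang(s), error = function(c)
        stop_odesio("parse_error", "cannot parse %s '%s'", what, s))
    })
  } else if (is.language(x) || is.numeric(x)) {
    x <- list(x)
  } else if (is.list(x)) {
    x <- lapply(x, function(e) {
      if (is.character(e)) str2lang(e) else e
    })
  } else {
    stop_odesio("invalid_expression", "cannot interpret %s", what)
  }
  x
}

#' Define a symbolic ODE model
#'
#' Constructs and validates a model of the form `x' = f(x, u, theta)`,
#' `y = h(x, u, theta)`.  Every free symbol appearing in `dynamics` or
#' `outputs` must be declared as a state, parameter, input or known
#' constant, expressions must be rational functions (operators `+ - * / ^`
#' with constant integer exponents), and there must be exactly one dynamics
#' expression per state.
#'
#' @param states Character vector of state names (non-empty, ordered).
#' @param parameters Character vector of unknown parameter names.
#' @param inputs Character vector of known input names.
#' @param dynamics Expressions for the state derivatives, as a character
#'   vector or a list of unevaluated R expressions, one per state.
#' @param outputs Output (measurement) expressions, same formats.
#' @param known_constants Named list of symbols with known exact rational
#'   values (e.g. `list(rhoS = "1/10")`); they are substituted before any
#'   analysis and are not part of the identifiability question.
#' @param input_derivatives Integer vector (recycled) giving, for each
#'   input, the number of derivatives that may be nonzero.  `NA` (default)
#'   means a generic smooth input; `0` means a constant input.
#' @param name Model name used in reports.
#' @return An object of class `ode_model`.
#' @examples
#' m <- ode_model("x", dynamics = "-x", outputs = "x")
#' glv2 <- glv_model(2)
#' @export
ode_model <- function(states, parameters = character(), inputs = character(),
                      dynamics, outputs, known_constants = list(),
                      input_derivatives = NULL, name = "model") {
  states <- as.character(states)
  parameters <- as.character(parameters)
  inputs <- as.character(inputs)
  if (length(states) == 0L)
    stop_odesio("dimension_mismatch", "a model needs at least one state")
  known_constants <- as.list(known_constants)
  kc_names <- names(known_constants)
  if (length(known_constants) > 0 &&
      (is.null(kc_names) || any(kc_names == "")))
    stop_odesio("invalid_expression", "known constants must be named")
  known_constants <- lapply(known_constants, function(v) {
    if (is.character(v)) v <- str2lang(v)
    if (is.numeric(v)) v <- as.numeric(v)
    check_expr_ops(v, "known constant")
    if (length(all.vars(v)) > 0)
      stop_odesio("invalid_expression", "known constants must be numeric")
    v
  })

  all_syms <- c(states, parameters, inputs, kc_names)
  dup <- all_syms[duplicated(all_syms)]
  if (length(dup) > 0)
    stop_odesio("invalid_expression", "duplicate symbol(s): %s",
                paste(unique(dup), collapse = ", "))
  bad_names <- all_syms[make.names(all_syms) != all_syms]
  if (length(bad_names) > 0)
    stop_odesio("invalid_expression", "invalid symbol name(s): %s",
                paste(bad_names, collapse = ", "))
  # input-derivative symbols u_d1, u_d2, ... are generated internally
  for (u in inputs) {
    clash <- grepl(paste0("^", u, "_d[0-9]+$"), all_syms)
    if (any(clash))
      stop_odesio("invalid_expression",
                  "symbol '%s' clashes with derivative symbols of input '%s'",
                  all_syms[clash][1], u)
  }

  dynamics <- normalize_exprs(dynamics, "dynamics")
  outputs <- normalize_exprs(outputs, "output")
  if (length(dynamics) != length(states))
    stop_odesio("dimension_mismatch",
                "%d dynamics expression(s) for %d state(s)",
                length(dynamics), length(states))
  if (length(outputs) == 0L)
    stop_odesio("dimension_mismatch", "a model needs at least one output")

  for (e in c(dynamics, outputs)) {
    check_expr_ops(e)
    stray <- setdiff(free_symbols(e), all_syms)
    if (length(stray) > 0)
      stop_odesio("unknown_symbol",
                  "undeclared symbol(s) in model expressions: %s",
                  paste(stray, collapse = ", "))
  }

  if (is.null(input_derivatives)) input_derivatives <- rep(NA_integer_, length(inputs))
  input_derivatives <- rep_len(as.integer(input_derivatives),
                               length(inputs))
  if (any(!is.na(input_derivatives) & input_derivatives < 0))
    stop_odesio("invalid_expression",
                "input derivative counts must be nonnegative")
  names(input_derivatives) <- inputs

  structure(
    list(name = name, states = states, parameters = parameters,
         inputs = inputs, input_derivatives = input_derivatives,
         known_constants = known_constants, dynamics = dynamics,
         outputs = outputs),
    class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("ODE model '%s': n = %d state(s), p = %d parameter(s), q = %d input(s), m = %d output(s)\n",
              x$name, length(x$states), length(x$parameters),
              length(x$inputs), length(x$outputs)))
  for (i in seq_along(x$states))
    cat(sprintf("  d%s/dt = %s\n", x$states[i], deparse1(x$dynamics[[i]])))
  for (j in seq_along(x$outputs))
    cat(sprintf("  y%d = %s\n", j, deparse1(x$outputs[[j]])))
  if (length(x$known_constants) > 0)
    cat("  known:", paste(names(x$known_constants), "=",
                          vapply(x$known_constants, deparse1, ""),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Augment a model's state with its parameters
#'
#' Parameters are constant states: the augmented state is the states
#' followed by the parameters (this column order is fixed and used by every
#' downstream classification), and the augmented dynamics appends one
#' identically-zero derivative per parameter.
#'
#' @param model An `ode_model` (or an `aug_model`, returned unchanged).
#' @return An object of class `aug_model` with elements `base`,
#'   `aug_states` and `aug_dynamics`.
#' @export
augment <- function(model) {
  if (inherits(model, "aug_model")) return(model)
  stopifnot(inherits(model, "ode_model"))
  structure(
    list(base = model,
         aug_states = c(model$states, model$parameters),
         aug_dynamics = c(model$dynamics,
                          rep(list(0), length(model$parameters)))),
    class = "aug_model")
}

#' @export
print.aug_model <- function(x, ...) {
  cat(sprintf("Augmented model '%s': dimension n + p = %d\n",
              x$base$name, length(x$aug_states)))
  invisible(x)
}

#' Convert an augmented model back to a plain parameter-free model
#'
#' The parameters become genuine (constant) states; augmenting the result
#' again therefore adds zero further components.
#'
#' @param aug An `aug_model`.
#' @return An `ode_model` with `n + p` states and no parameters.
#' @export
as_ode_model <- function(aug) {
  stopifnot(inherits(aug, "aug_model"))
  b <- aug$base
  ode_model(states = aug$aug_states, parameters = character(),
            inputs = b$inputs, dynamics = aug$aug_dynamics,
            outputs = b$outputs, known_constants = b$known_constants,
            input_derivatives = b$input_derivatives,
            name = paste0(b$name, "_aug"))
}

#' Define a measurement (output) configuration
#'
#' @param label Short label used in reports (e.g. `"x1"` or `"RM"`).
#' @param expressions Output expressions over the model states, as a
#'   character vector or list of expressions.
#' @return An object of class `output_config`.
#' @export
output_config <- function(label, expressions) {
  expressions <- normalize_exprs(expressions, "output")
  if (length(expressions) == 0L)
    stop_odesio("dimension_mismatch", "an output configuration must be non-empty")
  structure(list(label = label, expressions = expressions),
            class = "output_config")
}

#' Replace a model's outputs with a measurement configuration
#'
#' @param model An `ode_model`.
#' @param config An `output_config` (or a character vector of output
#'   expressions, which is promoted to one).  Configuration expressions may
#'   reference model states only.
#' @return A new `ode_model`; the original is untouched.
#' @export
with_outputs <- function(model, config) {
  stopifnot(inherits(model, "ode_model"))
  if (is.character(config))
    config <- output_config(paste(config, collapse = ","), config)
  stopifnot(inherits(config, "output_config"))
  for (e in config$expressions) {
    check_expr_ops(e)
    stray <- setdiff(free_symbols(e), model$states)
    if (length(stray) > 0)
      stop_odesio("unknown_symbol",
                  "output configuration references non-state symbol(s): %s",
                  paste(stray, collapse = ", "))
  }
  model$outputs <- config$expressions
  model$config_label <- config$label
  model
}

# ------------------------------------------------------------- text format

#' Read / write models in the plain-text model format
#'
#' One statement per line; `#` starts a comment.  Statements:
#' \preformatted{
#' model NAME
#' states x1 x2 ...
#' params r1 r2 ...
#' input u1 [deriv N]          (or: inputs u1 u2 ...)
#' known rhoS = 4/10
#' ode x1 = r1*x1 + b11*x1*x1
#' out y1 = x1
#' }
#' Expressions use `+ - * / ^`, parentheses, and integer or rational
#' literals.  `parse_sio_model()` parses a character vector (one element
#' per line or a single string); `read_sio_model()` reads a file.
#'
#' @param text Character vector with the model description.
#' @return An `ode_model`.
#' @export
parse_sio_model <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  name <- NULL
  states <- character(); params <- character(); inputs <- character()
  ideriv <- integer(); known <- list()
  odes <- list(); outs <- list(); out_names <- character()

  perr <- function(ln, msg, ...)
    stop_odesio("parse_error", paste0("line %d: ", msg), ln, ...)
  parse_rhs <- function(s, ln) {
    e <- tryCatch(str2lang(s), error = function(c) NULL)
    if (is.null(e)) perr(ln, "cannot parse expression '%s'", s)
    e
  }

  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (line == "") next
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    kw <- toks[1]
    if (kw == "model") {
      if (length(toks) != 2) perr(ln, "expected 'model NAME'")
      name <- toks[2]
    } else if (kw == "states") {
      if (length(toks) < 2) perr(ln, "expected at least one state")
      states <- c(states, toks[-1])
    } else if (kw %in% c("params", "parameters")) {
      params <- c(params, toks[-1])
    } else if (kw %in% c("input", "inputs")) {
      rest <- toks[-1]
      if (length(rest) >= 3 && rest[2] == "deriv") {
        d <- suppressWarnings(as.integer(rest[3]))
        if (is.na(d) || d < 0) perr(ln, "invalid derivative count '%s'", rest[3])
        inputs <- c(inputs, rest[1]); ideriv <- c(ideriv, d)
        if (length(rest) > 3) perr(ln, "unexpected tokens after deriv count")
      } else {
        if (length(rest) < 1) perr(ln, "expected at least one input")
        inputs <- c(inputs, rest); ideriv <- c(ideriv, rep(NA_integer_, length(rest)))
      }
    } else if (kw == "known") {
      eq <- regmatches(line, regexec("^known[[:space:]]+([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.+)$", line))[[1]]
      if (length(eq) != 3) perr(ln, "expected 'known NAME = VALUE'")
      known[[eq[2]]] <- parse_rhs(eq[3], ln)
    } else if (kw == "ode") {
      eq <- regmatches(line, regexec("^ode[[:space:]]+([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.+)$", line))[[1]]
      if (length(eq) != 3) perr(ln, "expected 'ode STATE = EXPR'")
      if (!is.null(odes[[eq[2]]])) perr(ln, "duplicate ode for state '%s'", eq[2])
      odes[[eq[2]]] <- parse_rhs(eq[3], ln)
    } else if (kw == "out") {
      eq <- regmatches(line, regexec("^out[[:space:]]+([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.+)$", line))[[1]]
      if (length(eq) != 3) perr(ln, "expected 'out NAME = EXPR'")
      out_names <- c(out_names, eq[2])
      outs <- c(outs, list(parse_rhs(eq[3], ln)))
    } else {
      perr(ln, "unknown statement '%s'", kw)
    }
  }

  if (is.null(name))
    stop_odesio("parse_error", "line 1: missing 'model NAME' statement")
  if (length(states) == 0L)
    stop_odesio("parse_error", "line 1: missing 'states' statement")
  missing_odes <- setdiff(states, names(odes))
  if (length(missing_odes) > 0)
    stop_odesio("parse_error", "line 1: missing ode for state(s): %s",
                paste(missing_odes, collapse = ", "))
  stray_odes <- setdiff(names(odes), states)
  if (length(stray_odes) > 0)
    stop_odesio("parse_error", "line 1: ode for undeclared state(s): %s",
                paste(stray_odes, collapse = ", "))
  if (length(outs) == 0L)
    stop_odesio("parse_error", "line 1: missing 'out' statement")

  names(ideriv) <- inputs
  m <- ode_model(states = states, parameters = params, inputs = inputs,
                 dynamics = odes[states], outputs = outs,
                 known_constants = known, input_derivatives = ideriv,
                 name = name)
  m$output_names <- out_names
  m
}

#' @rdname parse_sio_model
#' @param file Path of a model file.
#' @export
read_sio_model <- function(file) {
  if (!file.exists(file))
    stop_odesio("parse_error", "model file '%s' does not exist", file)
  parse_sio_model(readLines(file, warn = FALSE))
}

#' @rdname parse_sio_model
#' @param model An `ode_model` to serialize.
#' @return `serialize_sio_model()` returns the model text as a character
#'   vector of lines; `parse_sio_model(serialize_sio_model(m))` is
#'   symbolically identical to `m`.
#' @export
serialize_sio_model <- function(model) {
  stopifnot(inherits(model, "ode_model"))
  lines <- c(paste("model", model$name),
             paste("states", paste(model$states, collapse = " ")))
  if (length(model$parameters) > 0)
    lines <- c(lines, paste("params", paste(model$parameters, collapse = " ")))
  for (u in model$inputs) {
    d <- model$input_derivatives[[u]]
    lines <- c(lines,
               if (is.na(d)) paste("input", u)
               else paste("input", u, "deriv", d))
  }
  for (k in names(model$known_constants))
    lines <- c(lines, paste("known", k, "=",
                            deparse1(model$known_constants[[k]])))
  for (i in seq_along(model$states))
    lines <- c(lines, paste("ode", model$states[i], "=",
                            deparse1(model$dynamics[[i]])))
  onames <- model$output_names %||% paste0("y", seq_along(model$outputs))
  for (j in seq_along(model$outputs))
    lines <- c(lines, paste("out", onames[j], "=",
                            deparse1(model$outputs[[j]])))
  lines
}

#' @rdname parse_sio_model
#' @export
write_sio_model <- function(model, file) {
  writeLines(serialize_sio_model(model), file)
  invisible(file)
}
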