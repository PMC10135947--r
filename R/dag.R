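# R-side interface to the hash-consed expression DAG.
#
# Model expressions are ordinary R language objects restricted to the
# arithmetic of rational functions (+ - * / ^ with integer exponents, and
# integer or rational literals).  They are compiled into a shared DAG held
# in C++; differentiation and exact prime-field evaluation happen there.

OP_CONST <- 0L; OP_VAR <- 1L; OP_ADD <- 2L; OP_SUB <- 3L
OP_MUL <- 4L; OP_DIV <- 5L; OP_NEG <- 6L; OP_POW <- 7L

dag_new <- function(vars = character()) cpp_dag_create(vars)

dag_vars <- function(ptr) cpp_dag_vars(ptr)

dag_var_index <- function(ptr, name) match(name, cpp_dag_vars(ptr))

# Register a numeric literal; non-integer decimals are converted to exact
# rationals (0.4 -> 4/10) so that no floating-point value ever enters the
# field arithmetic.
dag_num <- function(ptr, v) {
  if (!is.finite(v)) stop_odesio("invalid_expression", "non-finite literal")
  if (v == floor(v)) return(cpp_dag_const(ptr, v))
  for (d in 1:9) {
    num <- v * 10^d
    if (abs(num - round(num)) < 1e-9 * max(1, abs(num))) {
      return(cpp_dag_op(ptr, OP_DIV, cpp_dag_const(ptr, round(num)),
                        cpp_dag_const(ptr, 10^d)))
    }
  }
  stop_odesio("invalid_expression", "literal %g is not an exact rational", v)
}

# Compile an R expression into the DAG.  Unknown symbols either raise an
# error or (for internally generated symbols such as input derivatives) are
# registered on the fly when `allow_new = TRUE`.
dag_from_expr <- function(ptr, e, allow_new = FALSE) {
  rec <- function(e) {
    if (is.numeric(e)) {
      if (length(e) != 1L)
        stop_odesio("invalid_expression", "vector literal in expression")
      return(dag_num(ptr, as.numeric(e)))
    }
    if (is.name(e)) {
      nm <- as.character(e)
      idx <- dag_var_index(ptr, nm)
      if (is.na(idx)) {
        if (!allow_new)
          stop_odesio("unknown_symbol", "unknown symbol '%s'", nm)
        idx <- cpp_dag_add_var(ptr, nm)
      }
      return(cpp_dag_var(ptr, idx))
    }
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (fn == "(") return(rec(e[[2]]))
      if (length(e) == 2L) {
        if (fn == "-") return(cpp_dag_op(ptr, OP_NEG, rec(e[[2]]), 0L))
        if (fn == "+") return(rec(e[[2]]))
        stop_odesio("invalid_expression", "unsupported operator '%s'", fn)
      }
      if (length(e) == 3L) {
        if (fn == "^") {
          expo <- tryCatch(eval(e[[3]], baseenv()), error = function(c) NULL)
          if (is.null(expo) || length(expo) != 1L || !is.finite(expo) ||
              expo != floor(expo))
            stop_odesio("invalid_expression",
                        "exponent must be a constant integer")
          return(cpp_dag_op(ptr, OP_POW, rec(e[[2]]), as.integer(expo)))
        }
        op <- switch(fn, "+" = OP_ADD, "-" = OP_SUB, "*" = OP_MUL,
                     "/" = OP_DIV, NULL)
        if (is.null(op))
          stop_odesio("invalid_expression", "unsupported operator '%s'", fn)
        return(cpp_dag_op(ptr, op, rec(e[[2]]), rec(e[[3]])))
      }
    }
    stop_odesio("invalid_expression", "unsupported expression: %s",
                deparse1(e))
  }
  rec(e)
}

dag_diff <- function(ptr, id, var) {
  if (is.character(var)) {
    var <- dag_var_index(ptr, var)
    if (is.na(var)) return(cpp_dag_const(ptr, 0))
  }
  cpp_dag_diff(ptr, id, as.integer(var))
}

# Reconstruct an R expression from a DAG node.  Shared subgraphs are
# duplicated in the resulting tree, so this is only meant for inspection of
# moderate expressions (Lie derivatives of the small models, Jacobian
# entries); a hard cap guards against accidental exponential expansion.
dag_to_expr <- function(ptr, id, max_nodes = 200000L) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  count <- 0L
  vars <- cpp_dag_vars(ptr)
  rec <- function(id) {
    key <- as.character(id)
    if (!is.null(memo[[key]])) return(memo[[key]])
    count <<- count + 1L
    if (count > max_nodes)
      stop_odesio("invalid_expression", "expression too large to reconstruct")
    info <- cpp_dag_info(ptr, id)
    e <- switch(as.character(info$op),
      "0" = info$cval,
      "1" = as.name(vars[info$a1]),
      "2" = call("+", rec(info$a1), rec(info$a2)),
      "3" = call("-", rec(info$a1), rec(info$a2)),
      "4" = call("*", rec(info$a1), rec(info$a2)),
      "5" = call("/", rec(info$a1), rec(info$a2)),
      "6" = call("-", rec(info$a1)),
      "7" = call("^", rec(info$a1), info$a2))
    memo[[key]] <- e
    e
  }
  rec(id)
}

# Evaluate DAG nodes at a point of the prime field; `values` is a named or
# positional vector covering the DAG variables.  Returns a numeric vector of
# residues, or NULL if the point hits a pole (division by zero in GF(p)).
dag_eval <- function(ptr, ids, values, prime) {
  vars <- cpp_dag_vars(ptr)
  if (!is.null(names(values))) values <- values[vars]
  if (length(values) < length(vars) || anyNA(values))
    stop_odesio("invalid_expression", "missing values for DAG variables")
  res <- cpp_dag_eval(ptr, as.integer(ids), as.numeric(values), prime)
  if (!res$ok) return(NULL)
  res$values
}

# Substitute named symbols in an R expression by replacement expressions.
subst_symbols <- function(e, subs) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(subs)) return(subs[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- subst_symbols(e[[i]], subs)
    return(e)
  }
  e
}

# Free symbols of an expression (excluding function names).
free_symbols <- function(e) all.vars(e)

# Structural whitelist check for model expressions: only field arithmetic.
check_expr_ops <- function(e, where = "expression") {
  rec <- function(e) {
    if (is.numeric(e) || is.name(e)) return(invisible(TRUE))
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (fn == "(") return(rec(e[[2]]))
      if (length(e) == 2L && fn %in% c("-", "+")) return(rec(e[[2]]))
      if (length(e) == 3L && fn %in% c("+", "-", "*", "/", "^")) {
        rec(e[[2]]); rec(e[[3]])
        return(invisible(TRUE))
      }
    }
    stop_odesio("invalid_expression",
                "%s contains unsupported construct: %s", where, deparse1(e))
  }
  rec(e)
}

# Symbolic-equality oracle: two expressions over the same symbols are
# compared by exact evaluation at several random points of GF(p).  This is
# probabilistically complete for rational functions and is used by tests
# and by the model-file round-trip checks.
expr_equal <- function(e1, e2, vars = union(all.vars(e1), all.vars(e2)),
                       n_points = 4L, seed = 17L,
                       prime = sio_prime("modular")) {
  ptr <- dag_new(vars)
  id1 <- dag_from_expr(ptr, e1)
  id2 <- dag_from_expr(ptr, e2)
  if (id1 == id2) return(TRUE)   # hash-consing already identified them
  with_seed(seed, {
    hits <- 0L
    tries <- 0L
    while (hits < n_points && tries < 8L * n_points) {
      tries <- tries + 1L
      v <- dag_eval(ptr, c(id1, id2), draw_points(length(vars)), prime)
      if (is.null(v)) next      # pole of one of the expressions; redraw
      if (v[1] != v[2]) return(FALSE)
      hits <- hits + 1L
    }
    if (hits == 0L)
      stop_odesio("degenerate", "could not find a regular comparison point")
    TRUE
  })
}
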