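# Differential-geometry engine
#
# The observability-identifiability matrix stacks the Jacobians, with
# respect to the augmented state (states followed by parameters), of the
# outputs and of their successive Lie derivatives along the dynamics.  Full
# generic rank n + p certifies FISPO; otherwise each augmented component is
# classified by removing its column and recomputing the rank: a rank drop
# marks the parameter as structurally locally identifiable (the state as
# observable), an unchanged rank marks it unidentifiable (unobservable).
#
# Generic rank is never computed by floating-point decompositions: the
# symbols are specialized at independent random integers in [2, 2^20] and
# the rank is obtained by exact Gaussian elimination in GF(p), taking the
# maximum over a small number of independent specializations (rank at a
# random point can only underestimate the generic rank, and only on a
# measure-zero locus).

u_deriv_name <- function(u, j) if (j == 0) u else paste0(u, "_d", j)

dag_is_zero <- function(ptr, id) {
  info <- cpp_dag_info(ptr, id)
  info$op == OP_CONST && info$cval == 0
}

# Shared compilation of an augmented model into a DAG context.
engine_ctx <- function(aug) {
  model <- aug$base
  ptr <- dag_new(aug$aug_states)
  for (u in model$inputs) cpp_dag_add_var(ptr, u)
  subs <- model$known_constants
  f_ids <- vapply(aug$aug_dynamics, function(e)
    dag_from_expr(ptr, subst_symbols(e, subs)), integer(1))
  h_ids <- vapply(model$outputs, function(e)
    dag_from_expr(ptr, subst_symbols(e, subs)), integer(1))
  st <- new.env(parent = emptyenv())
  st$umax <- stats::setNames(rep(0L, length(model$inputs)), model$inputs)
  list(ptr = ptr, f_ids = f_ids, h_ids = h_ids, aug = aug, model = model,
       st = st)
}

# One Lie-derivative step applied to a vector of DAG nodes:
#   L_f h = (dh/dx~) f~ + sum_j (dh/du^(j)) u^(j+1)
# where u^(j+1) is identically zero beyond the input's nonzero-derivative
# count.  Parameter components of f~ vanish, so the state sum suffices.
lie_step <- function(ec, ids) {
  ptr <- ec$ptr
  model <- ec$model
  n <- length(model$states)
  vapply(ids, function(h) {
    total <- cpp_dag_const(ptr, 0)
    for (i in seq_len(n)) {
      dh <- cpp_dag_diff(ptr, h, i)
      if (dag_is_zero(ptr, dh)) next
      total <- cpp_dag_op(ptr, OP_ADD, total,
                          cpp_dag_op(ptr, OP_MUL, dh, ec$f_ids[i]))
    }
    for (u in model$inputs) {
      maxd <- model$input_derivatives[[u]]
      for (j in 0:ec$st$umax[[u]]) {
        idx <- dag_var_index(ptr, u_deriv_name(u, j))
        dh <- cpp_dag_diff(ptr, h, idx)
        if (dag_is_zero(ptr, dh)) next
        if (!is.na(maxd) && j + 1 > maxd) next  # u^(j+1) identically zero
        nxt <- u_deriv_name(u, j + 1)
        nidx <- dag_var_index(ptr, nxt)
        if (is.na(nidx)) {
          nidx <- cpp_dag_add_var(ptr, nxt)
          ec$st$umax[[u]] <- j + 1L
        }
        total <- cpp_dag_op(ptr, OP_ADD, total,
                            cpp_dag_op(ptr, OP_MUL, dh, cpp_dag_var(ptr, nidx)))
      }
    }
    total
  }, integer(1))
}

#' Lie derivatives of output expressions along a model's dynamics
#'
#' Computes the order-`order` Lie derivative of each expression in `exprs`
#' along the augmented vector field of `model`.  For autonomous models this
#' is the total time derivative taken `order` times; for models with inputs
#' the chain-rule terms in the input derivatives `u', u'', ...` are
#' included, truncated at each input's nonzero-derivative count.
#'
#' @param exprs Expressions (character vector or list of expressions) over
#'   the model symbols.
#' @param model An `ode_model` or `aug_model`.
#' @param order Derivative order (a positive integer).
#' @return A list of unevaluated R expressions.
#' @examples
#' m <- ode_model("x", dynamics = "-x", outputs = "x")
#' lie_derivative("x", m, 2)   # x
#' @export
lie_derivative <- function(exprs, model, order = 1L) {
  order <- as.integer(order)
  if (is.na(order) || order < 1L)
    stop_odesio("order_negative", "order must be a positive integer")
  aug <- augment(model)
  ec <- engine_ctx(aug)
  ids <- vapply(normalize_exprs(exprs, "expression"), function(e) {
    check_expr_ops(e)
    dag_from_expr(ec$ptr, subst_symbols(e, aug$base$known_constants),
                  allow_new = TRUE)
  }, integer(1))
  for (b in seq_len(order)) ids <- lie_step(ec, ids)
  lapply(ids, function(id) dag_to_expr(ec$ptr, id))
}

# Draw (or extend) one specialization covering all DAG variables; returns
# the value vector, retrying on poles of the evaluated nodes.
draw_full <- function(ptr) draw_points(length(dag_vars(ptr)))

eval_entry_matrix <- function(ptr, entries, values, prime) {
  v <- dag_eval(ptr, as.vector(entries), values, prime)
  if (is.null(v)) return(NULL)
  matrix(v, nrow = nrow(entries), ncol = ncol(entries))
}

#' Build the observability-identifiability matrix
#'
#' Stacks the Jacobian blocks of the outputs and their Lie derivatives with
#' respect to the augmented state, one block per derivative order.  With
#' `max_order = "auto"` blocks are added until one more order no longer
#' increases the generic rank (the rank of the full matrix can never exceed
#' n + p, and n + p - 1 orders are always sufficient, so the loop is
#' bounded either way).
#'
#' @param model An `ode_model`.
#' @param config Optional `output_config` replacing the model outputs.
#' @param max_order `"auto"` (default) or an integer number of derivative
#'   orders, at most `n + p - 1`.
#' @param seed,trials Random specializations used for the rank probes.
#' @param field Working field, see [sio_prime()].
#' @return An object of class `oi_matrix` with the symbolic entries (as DAG
#'   nodes), the augmented-state column labels, the derivative order used
#'   and the specializations at which it was evaluated.
#' @export
oi_matrix <- function(model, config = NULL, max_order = "auto", seed = 1L,
                      trials = 2L, field = "modular") {
  if (!is.null(config)) model <- with_outputs(model, config)
  prime <- sio_prime(field)
  aug <- augment(model)
  np <- length(aug$aug_states)
  m <- length(model$outputs)
  auto <- identical(max_order, "auto")
  if (!auto) {
    max_order <- as.integer(max_order)
    if (max_order < 0L || max_order > np - 1L)
      stop_odesio("invalid_expression",
                  "max_order must lie in [0, n + p - 1]")
  }

  ec <- engine_ctx(aug)
  ptr <- ec$ptr

  jac_block <- function(ids) {
    t(vapply(ids, function(h)
      vapply(seq_len(np), function(j) cpp_dag_diff(ptr, h, j), integer(1)),
      integer(np)))
  }

  with_seed(seed, {
    lev <- ec$h_ids
    entries <- jac_block(lev)
    trial_vals <- lapply(seq_len(trials), function(t) draw_full(ptr))
    evaluate <- function() {
      mats <- vector("list", trials)
      for (t in seq_len(trials)) {
        # extend this trial's draws to newly registered input derivatives
        nv <- length(dag_vars(ptr))
        if (length(trial_vals[[t]]) < nv)
          trial_vals[[t]] <<- c(trial_vals[[t]],
                                draw_points(nv - length(trial_vals[[t]])))
        mat <- NULL
        for (try in 1:5) {
          mat <- eval_entry_matrix(ptr, entries, trial_vals[[t]], prime)
          if (!is.null(mat)) break
          trial_vals[[t]] <<- draw_points(nv)   # pole: re-specialize
        }
        if (is.null(mat))
          stop_odesio("degenerate",
                      "all specializations hit a singular locus")
        mats[[t]] <- mat
      }
      mats
    }

    mats <- evaluate()
    rank <- max(vapply(mats, function(M) cpp_mod_rank(M, prime), integer(1)))
    k <- 0L
    repeat {
      if (rank >= np) break
      if (auto && k >= np - 1L) break
      if (!auto && k >= max_order) break
      lev <- lie_step(ec, lev)
      entries <- rbind(entries, jac_block(lev))
      k <- k + 1L
      mats <- evaluate()
      new_rank <- max(vapply(mats, function(M) cpp_mod_rank(M, prime),
                             integer(1)))
      if (auto && new_rank == rank) { rank <- new_rank; break }
      rank <- new_rank
    }

    structure(
      list(ptr = ptr, entries = entries,
           column_labels = aug$aug_states, order_used = k,
           n_outputs = m, aug = aug, prime = prime, seed = seed,
           trials = trials, trial_values = trial_vals,
           trial_matrices = mats, rank = rank),
      class = "oi_matrix")
  })
}

#' Symbolic entries of an observability-identifiability matrix
#'
#' Reconstructs the matrix entries as R expressions.  Intended for
#' inspection of small models; entries of large models can be exponentially
#' bigger as trees than as shared graphs, so a node cap applies.
#'
#' @param oi An `oi_matrix`.
#' @param max_nodes Reconstruction cap.
#' @return A matrix of unevaluated R expressions.
#' @export
oi_entries <- function(oi, max_nodes = 200000L) {
  stopifnot(inherits(oi, "oi_matrix"))
  out <- matrix(list(), nrow(oi$entries), ncol(oi$entries))
  for (i in seq_len(nrow(oi$entries)))
    for (j in seq_len(ncol(oi$entries)))
      out[[i, j]] <- dag_to_expr(oi$ptr, oi$entries[i, j], max_nodes)
  colnames(out) <- oi$column_labels
  out
}

#' @export
print.oi_matrix <- function(x, ...) {
  cat(sprintf("Observability-identifiability matrix: %d x %d (orders 0..%d), generic rank %d of %d\n",
              nrow(x$entries), ncol(x$entries), x$order_used, x$rank,
              length(x$column_labels)))
  invisible(x)
}

#' Generic rank of an observability-identifiability matrix
#'
#' Evaluates the symbolic matrix at `trials` fresh random integer points
#' (componentwise uniform on \[2, 2^20\]) and returns the maximum exact
#' GF(p) rank observed.  Specializations that hit a pole of a rational
#' entry are redrawn; after five failures per trial a degeneracy error is
#' raised.
#'
#' @param oi An `oi_matrix`.
#' @param seed Seed for the specializations.
#' @param trials Number of independent specializations (at least 1).
#' @return The generic rank as an integer.
#' @export
generic_rank <- function(oi, seed = 1L, trials = 2L) {
  stopifnot(inherits(oi, "oi_matrix"))
  if (trials < 1L) stop_odesio("invalid_expression", "trials must be >= 1")
  with_seed(seed, {
    ranks <- integer(trials)
    for (t in seq_len(trials)) {
      mat <- NULL
      for (try in 1:5) {
        mat <- eval_entry_matrix(oi$ptr, oi$entries, draw_full(oi$ptr),
                                 oi$prime)
        if (!is.null(mat)) break
      }
      if (is.null(mat))
        stop_odesio("degenerate", "all specializations hit a singular locus")
      ranks[t] <- cpp_mod_rank(mat, oi$prime)
    }
    max(ranks)
  })
}

#' Classify a model with the Lie-derivative engine
#'
#' Builds the observability-identifiability matrix (derivative orders are
#' added until the generic rank stabilizes), computes its generic rank, and
#' classifies every parameter and state by the column-removal test.
#'
#' @inheritParams oi_matrix
#' @return An object of class `sio_result`; see [sio()].
#' @export
sio_lie <- function(model, config = NULL, seed = 1L, trials = 2L,
                    field = "modular", max_order = "auto") {
  oi <- oi_matrix(model, config = config, max_order = max_order,
                  seed = seed, trials = trials, field = field)
  np <- length(oi$column_labels)
  drops <- lapply(oi$trial_matrices, function(M)
    cpp_mod_rank_drop(M, oi$prime))
  full <- max(vapply(drops, `[`, integer(1), 1L))
  col_ranks <- apply(do.call(rbind, lapply(drops, function(d) d[-1])), 2, max)
  names(col_ranks) <- oi$column_labels
  new_sio_result(
    model = oi$aug$base, engine = "lie", seed = seed, rank = full,
    col_ranks = col_ranks, prime = oi$prime,
    evidence = list(order_used = oi$order_used, trials = trials,
                    specializations = lapply(oi$trial_values, function(v)
                      stats::setNames(v, dag_vars(oi$ptr)[seq_along(v)]))))
}
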