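# Model zoo: the microbial community model families analysed in the
# reference classification tables, at the dimensions used there.

#' Generalized Lotka-Volterra (gLV) model
#'
#' Species-species interaction model with per-capita growth and pairwise
#' interactions:
#'   dx_i/dt = r_i x_i + sum_j b_ij x_i x_j.
#' One growth rate `r_i` per species and one interaction rate `b_ij` per
#' ordered pair (the matrix is not assumed symmetric), so p = n + n^2.
#' Default outputs measure every state.
#'
#' @param n Number of species (>= 1).
#' @return An `ode_model` with states `x1..xn`, parameters `r1..rn` and
#'   `b11..bnn`.
#' @export
glv_model <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop_odesio("dimension_mismatch", "gLV needs n >= 1 species")
  states <- paste0("x", seq_len(n))
  r <- paste0("r", seq_len(n))
  b <- as.vector(t(outer(seq_len(n), seq_len(n),
                         function(i, j) paste0("b", i, j))))
  dyn <- vapply(seq_len(n), function(i) {
    inter <- paste(vapply(seq_len(n), function(j)
      sprintf("b%d%d*x%d*x%d", i, j, i, j), ""), collapse = " + ")
    sprintf("r%d*x%d + %s", i, i, inter)
  }, "")
  ode_model(states = states, parameters = c(r, b), dynamics = dyn,
            outputs = states, name = sprintf("glv%d", n))
}

#' Composite Lotka-Volterra (cLV) model
#'
#' Relative-abundance (compositional) counterpart of the gLV model,
#' obtained through the additive log-ratio transform.  With relative
#' abundances pi_i summing to one, the last one is eliminated
#' (pi_n = 1 - sum of the others) and the reduced system reads
#'   d pi_i/dt = pi_i (F_i - Fbar),   F_i = g_i + sum_j A_ij pi_j
#'   (+ sum_k B_ik u_k with measured external perturbations),
#' with Fbar = sum_{j<n} pi_j F_j.  Only the reduced (barred) parameters
#' are structural unknowns: the reduction makes the original gLV
#' parameters non-recoverable by construction.  The interaction index j
#' keeps its full range 1..n, with pi_n substituted.
#'
#' @param n Number of species (>= 2); the model has n - 1 states.
#' @param input If `TRUE`, include one measured time-varying input `u1`
#'   with perturbation parameters `B11..B(n-1)1`.
#' @return An `ode_model` with states `pi1..pi(n-1)`.
#' @export
clv_model <- function(n, input = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    stop_odesio("dimension_mismatch", "cLV needs n >= 2 species")
  ns <- n - 1L
  states <- paste0("pi", seq_len(ns))
  pin <- paste0("(1 - ", paste(states, collapse = " - "), ")")
  pi_of <- function(j) if (j == n) pin else paste0("pi", j)
  Fi <- vapply(seq_len(ns), function(i) {
    terms <- c(sprintf("g%d", i),
               vapply(seq_len(n), function(j)
                 sprintf("A%d%d*%s", i, j, pi_of(j)), ""))
    if (input) terms <- c(terms, sprintf("B%d1*u1", i))
    paste(terms, collapse = " + ")
  }, "")
  Fbar <- paste(vapply(seq_len(ns), function(j)
    sprintf("pi%d*(%s)", j, Fi[j]), ""), collapse = " + ")
  dyn <- vapply(seq_len(ns), function(i)
    sprintf("pi%d*((%s) - (%s))", i, Fi[i], Fbar), "")
  params <- c(paste0("g", seq_len(ns)),
              as.vector(t(outer(seq_len(ns), seq_len(n),
                                function(i, j) paste0("A", i, j)))))
  if (input) params <- c(params, paste0("B", seq_len(ns), "1"))
  ode_model(states = states, parameters = params,
            inputs = if (input) "u1" else character(),
            dynamics = dyn, outputs = states,
            name = sprintf("clv%d%s", n, if (input) "u" else ""))
}

#' Quadratic species-metabolite interaction (QSMI) model
#'
#' Consumer-resource model with quadratic kinetics, constant dilution of
#' species (`d_i`) and metabolites (`ds_j`), a constant influx `f_j` per
#' metabolite, and by-product production terms `phi_ilj` (metabolite l is
#' transformed into metabolite j in a reaction involving species i):
#'   dx_i/dt = x_i (sum_j psi_ij m_j - d_i)
#'   dm_j/dt = m_j (-sum_i k_ij x_i - ds_j) + f_j
#'             + sum_i sum_l phi_ilj x_i m_l.
#' Note that the consumption term `k_ij x_i m_j` and the diagonal
#' by-product term `phi_ijj x_i m_j` contribute the same monomial, which
#' is why those parameter pairs can never be separately identifiable.
#'
#' @param n Number of species.
#' @param nm Number of metabolites.
#' @return An `ode_model` with states `x1..xn, m1..mnm`.
#' @export
qsmi_model <- function(n, nm) {
  n <- as.integer(n); nm <- as.integer(nm)
  if (is.na(n) || n < 1L || is.na(nm) || nm < 1L)
    stop_odesio("dimension_mismatch", "QSMI needs n >= 1 and nm >= 1")
  states <- c(paste0("x", seq_len(n)), paste0("m", seq_len(nm)))
  dyn_x <- vapply(seq_len(n), function(i) {
    growth <- paste(vapply(seq_len(nm), function(j)
      sprintf("psi%d%d*m%d", i, j, j), ""), collapse = " + ")
    sprintf("x%d*(%s - d%d)", i, growth, i)
  }, "")
  dyn_m <- vapply(seq_len(nm), function(j) {
    cons <- paste(vapply(seq_len(n), function(i)
      sprintf("k%d%d*x%d", i, j, i), ""), collapse = " - ")
    prod <- paste(unlist(lapply(seq_len(n), function(i)
      vapply(seq_len(nm), function(l)
        sprintf("phi%d%d%d*x%d*m%d", i, l, j, i, l), ""))),
      collapse = " + ")
    sprintf("m%d*(-%s - ds%d) + f%d + %s", j, cons, j, j, prod)
  }, "")
  params <- c(as.vector(t(outer(seq_len(n), seq_len(nm),
                                function(i, j) paste0("psi", i, j)))),
              paste0("d", seq_len(n)),
              as.vector(t(outer(seq_len(n), seq_len(nm),
                                function(i, j) paste0("k", i, j)))),
              paste0("ds", seq_len(nm)),
              paste0("f", seq_len(nm)),
              unlist(lapply(seq_len(n), function(i)
                lapply(seq_len(nm), function(l)
                  paste0("phi", i, l, seq_len(nm))))))
  ode_model(states = states, parameters = params, dynamics = c(dyn_x, dyn_m),
            outputs = states, name = sprintf("qsmi%d_%d", n, nm))
}

#' Species-metabolite interaction model with Monod kinetics (MSMI)
#'
#' Consumer-resource model where uptake saturates with Monod-type terms.
#' Under the default reading (`reading = "product"`) the half-saturation
#' acts on the species-metabolite product:
#'   dx_i/dt = x_i (sum_j V_ij m_j / (K_ij + m_j x_i) - d_i)
#'   dm_j/dt = -sum_i Vs_ij x_i m_j / (Ks_ij + x_i m_j) - ds_j m_j + f_j
#'             + sum_i sum_l phi_ilj x_i m_l / (Ks_il + x_i m_l).
#' Note that consumption of metabolite j and its diagonal by-product term
#' (l = j) then have the same functional form, so `Vs_ij` and `phi_ijj`
#' only enter through their difference and can never be separately
#' identified -- the Monod analogue of the `k`/diagonal-`phi` degeneracy
#' of the quadratic model.  `reading = "classic"` uses instead the
#' textbook Monod denominators `K_ij + m_j` and `Ks_ij + m_j`, which
#' removes that degeneracy; the reproduction reports record which reading
#' is in force.
#'
#' By default the by-product half-saturation constants are shared with the
#' consumption family `Ks` (indexed by species and source metabolite),
#' which keeps the parameter inventory equal to the one used in the
#' reference classification tables; `shared_byproduct_K = FALSE`
#' introduces an independent family `Kb_il` instead.
#'
#' @param n Number of species.
#' @param nm Number of metabolites.
#' @param reading `"product"` (default) or `"classic"`; see Details.
#' @param shared_byproduct_K Share `Ks` between consumption and by-product
#'   terms (default) or use an independent `Kb` family.
#' @return An `ode_model` with states `x1..xn, m1..mnm`.
#' @export
msmi_model <- function(n, nm, reading = c("product", "classic"),
                       shared_byproduct_K = TRUE) {
  n <- as.integer(n); nm <- as.integer(nm)
  reading <- match.arg(reading)
  if (is.na(n) || n < 1L || is.na(nm) || nm < 1L)
    stop_odesio("dimension_mismatch", "MSMI needs n >= 1 and nm >= 1")
  states <- c(paste0("x", seq_len(n)), paste0("m", seq_len(nm)))
  kb <- function(i, l) if (shared_byproduct_K) sprintf("Ks%d%d", i, l)
                       else sprintf("Kb%d%d", i, l)
  dyn_x <- vapply(seq_len(n), function(i) {
    growth <- paste(vapply(seq_len(nm), function(j)
      if (reading == "product")
        sprintf("V%d%d*m%d/(K%d%d + m%d*x%d)", i, j, j, i, j, j, i)
      else
        sprintf("V%d%d*m%d/(K%d%d + m%d)", i, j, j, i, j, j), ""),
      collapse = " + ")
    sprintf("x%d*(%s - d%d)", i, growth, i)
  }, "")
  dyn_m <- vapply(seq_len(nm), function(j) {
    cons <- paste(vapply(seq_len(n), function(i)
      if (reading == "product")
        sprintf("Vs%d%d*x%d*m%d/(Ks%d%d + x%d*m%d)", i, j, i, j, i, j, i, j)
      else
        sprintf("Vs%d%d*x%d*m%d/(Ks%d%d + m%d)", i, j, i, j, i, j, j), ""),
      collapse = " - ")
    prod <- paste(unlist(lapply(seq_len(n), function(i)
      vapply(seq_len(nm), function(l)
        sprintf("phi%d%d%d*x%d*m%d/(%s + x%d*m%d)",
                i, l, j, i, l, kb(i, l), i, l), ""))),
      collapse = " + ")
    sprintf("-%s - ds%d*m%d + f%d + %s", cons, j, j, j, prod)
  }, "")
  fam <- function(stem) as.vector(t(outer(seq_len(n), seq_len(nm),
                                          function(i, j) paste0(stem, i, j))))
  params <- c(fam("V"), fam("K"), paste0("d", seq_len(n)),
              fam("Vs"), fam("Ks"), paste0("ds", seq_len(nm)),
              paste0("f", seq_len(nm)),
              unlist(lapply(seq_len(n), function(i)
                lapply(seq_len(nm), function(l)
                  paste0("phi", i, l, seq_len(nm))))))
  if (!shared_byproduct_K) params <- c(params, fam("Kb"))
  ode_model(states = states, parameters = params, dynamics = c(dyn_x, dyn_m),
            outputs = states, name = sprintf("msmi%d_%d", n, nm))
}

#' Phage cocktail (PC) therapy model
#'
#' Five-state model of phage therapy: sensitive (`S`) and therapy-resistant
#' (`R`) bacteria, their targeting phages (`PS`, `PR`) and the host immune
#' response (`I`).  Bacteria grow logistically (capacity `KC`), sensitive
#' cells mutate to resistant with probability `mu`, phages attack through
#' the saturating response `F(P) = phi P / (1 + P / PC)`, and the immune
#' response (activation rate `alpha`, saturation `KI`) kills both strains
#' with kinetics parameterized by `eps` and `KD`.  The phage injection
#' rates `rhoS` and `rhoR` are dosing quantities and enter as known
#' constants (distinct nonzero rationals), not as unknowns.
#'
#' The scaled variant (`scaled = TRUE`) is the nondimensionalized model
#' with states `x1..x5`, reparameterized constants
#' (`KCD, KPD, epst, psi, KND, q`) and two measured dosing inputs
#' `u1, u2`.
#'
#' @param scaled Build the scaled (nondimensionalized) variant.
#' @return An `ode_model`.
#' @export
pc_model <- function(scaled = FALSE) {
  if (!scaled) {
    FPS <- "(phi*PS/(1 + PS/PC))"
    FPR <- "(phi*PR/(1 + PR/PC))"
    dyn <- c(
      S  = sprintf("r*S*(1 - (S + R)/KC)*(1 - mu) - S*%s - eps*I*S/(1 + (S + R)/KD)", FPS),
      R  = sprintf("rp*R + mu*r*S*(1 - (S + R)/KC) - R*%s - eps*I*R/(1 + (S + R)/KD)", FPR),
      PS = sprintf("beta*S*%s - phi*S*PS - omega*PS + rhoS", FPS),
      I  = "alpha*I*(1 - I/KI)*(S + R)/(S + R + KN)",
      PR = sprintf("beta*R*%s - phi*R*PR - omega*PR + rhoR", FPR))
    return(ode_model(
      states = c("S", "R", "PS", "I", "PR"),
      parameters = c("r", "rp", "mu", "eps", "KC", "KD", "KI", "KN",
                     "alpha", "beta", "phi", "omega", "PC"),
      dynamics = dyn, outputs = c("S", "R", "PS", "I", "PR"),
      known_constants = list(rhoS = "1/10", rhoR = "1/5"),
      name = "pc"))
  }
  I3 <- "(psi*x3/(1 + x3))"
  I5 <- "(psi*x5/(1 + x5))"
  dyn <- c(
    x1 = sprintf("r*x1*(1 - (x1 + x2)/KCD)*(1 - mu) - KPD*x1*%s - epst*x4*x1/(1 + x1 + x2)", I3),
    x2 = sprintf("rp*x2 + r*x1*(1 - (x1 + x2)/KCD)*mu - KPD*x2*%s - epst*x4*x2/(1 + x1 + x2)", I5),
    x3 = sprintf("beta*x1*%s - psi*x1*x3 - omega*x3 + q*u1", I3),
    x4 = "alpha*x4*(1 - x4)*(x1 + x2)/(x1 + x2 + KND)",
    x5 = sprintf("beta*x2*%s - psi*x2*x5 - omega*x5 + q*u2", I5))
  ode_model(
    states = paste0("x", 1:5),
    parameters = c("r", "rp", "mu", "KCD", "KPD", "epst", "beta", "psi",
                   "omega", "q", "alpha", "KND"),
    inputs = c("u1", "u2"),
    dynamics = dyn, outputs = paste0("x", 1:5),
    name = "pc_scaled")
}

#' Build a zoo model by family name
#'
#' @param family One of `"glv"`, `"clv"`, `"qsmi"`, `"msmi"`, `"pc"`.
#' @param n,nm Dimensions where applicable.
#' @param input For `"clv"`: include the measured input.
#' @param scaled For `"pc"`: the scaled variant.
#' @param ... Further arguments for the family constructor.
#' @return An `ode_model`.
#' @export
zoo_model <- function(family, n = 2L, nm = 1L, input = FALSE,
                      scaled = FALSE, ...) {
  switch(family,
         glv = glv_model(n),
         clv = clv_model(n, input = input),
         qsmi = qsmi_model(n, nm),
         msmi = msmi_model(n, nm, ...),
         pc = pc_model(scaled = scaled),
         stop_odesio("unknown_kind", "unknown model family '%s'", family))
}
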