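# Probabilistic algebraic engine: variational system, specialization,
# power-series solution, coefficient Jacobian and transcendence degree.

p_mod <- sio_prime("modular")
inv <- function(a) odesio:::cpp_mod_inv(a, p_mod)
mfrac <- function(num, den) (num %% p_mod * inv(den)) %% p_mod

test_that("the variational Jacobian is the symbolic df/dx with zero parameter rows", {
  vs <- variational_system(ode_model("x", dynamics = "-x", outputs = "x"))
  expect_true(expr_equal(vs$jacobian[[1, 1]], quote(-1)))

  vs2 <- variational_system(ode_model("x", parameters = "th",
                                      dynamics = "th*x", outputs = "x"))
  expect_true(expr_equal(vs2$jacobian[[1, 1]], quote(th)))
  expect_true(expr_equal(vs2$jacobian[[1, 2]], quote(x)))
  expect_identical(vs2$jacobian[[2, 1]], 0)
  expect_identical(vs2$jacobian[[2, 2]], 0)

  # gLV n=2: 8x8 with exactly the two state rows nonzero
  vsg <- variational_system(glv_model(2))
  nonzero_rows <- which(apply(vsg$jacobian, 1, function(r)
    any(!vapply(r, identical, logical(1), 0))))
  expect_identical(nonzero_rows, c(x1 = 1L, x2 = 2L))
})

test_that("specialization is seed-deterministic and respects input degrees", {
  vs <- variational_system(clv_model(2, input = TRUE))
  ss1 <- specialize(vs, seed = 5)
  ss2 <- specialize(vs, seed = 5)
  expect_identical(ss1$x0, ss2$x0)
  expect_identical(ss1$input_polys, ss2$input_polys)
  expect_false(identical(ss1$x0, specialize(vs, seed = 6)$x0))
  # generic input: polynomial degree n + p
  expect_length(ss1$input_polys$u1, length(ss1$aug$aug_states) + 1L)

  m <- ode_model("x", inputs = "u", dynamics = "u*x", outputs = "x",
                 input_derivatives = 3L)
  ss3 <- specialize(variational_system(m), seed = 5)
  expect_length(ss3$input_polys$u, 4L)   # c0 + c1 t + c2 t^2 + c3 t^3

  # no inputs: only numeric initial conditions
  ss4 <- specialize(variational_system(glv_model(2)), seed = 5)
  expect_length(ss4$input_polys, 0)
  expect_length(ss4$x0, 8)
})

test_that("series solutions match closed forms in the field", {
  # x' = x, x(0) = 1: e^t
  m <- ode_model("x", dynamics = "x", outputs = "x")
  ser <- sio_output_series(m, list(x = 1), order = 4)
  expect_equal(unname(ser[1, ]),
               c(1, 1, mfrac(1, 2), mfrac(1, 6), mfrac(1, 24)))

  # x' = th x^2, th = 2, x(0) = 1: 1/(1 - 2t), geometric coefficients
  m2 <- ode_model("x", parameters = "th", dynamics = "th*x^2", outputs = "x")
  ser2 <- sio_output_series(m2, list(x = 1, th = 2), order = 3)
  expect_equal(unname(ser2[1, ]), c(1, 2, 4, 8))

  # x' = -x observed through y = x: coefficients of e^{-t}
  m3 <- ode_model("x", dynamics = "-x", outputs = "x")
  ser3 <- sio_output_series(m3, list(x = 1), order = 3)
  expect_equal(unname(ser3[1, ]),
               c(1, p_mod - 1, mfrac(1, 2), (p_mod - mfrac(1, 6)) %% p_mod))
})

test_that("sensitivity series solve the variational system", {
  # x' = th x at th = 1, x(0) = 1: dx/dth(t) = t e^t -> 0, 1, 1, 1/2
  m <- ode_model("x", parameters = "th", dynamics = "th*x", outputs = "x")
  vs <- variational_system(m)
  ss <- specialize(vs, seed = 1)
  ss$x0 <- c(x = 1, th = 1)
  sol <- series_solve(ss, order = 3)
  X <- sol$sensitivity_series   # rows: (i-1)*np + j of X[i,j]
  expect_equal(unname(X[2, ]), c(0, 1, 1, mfrac(1, 2)))
  # sensitivity starts at the identity
  expect_equal(unname(X[c(1, 4), 1]), c(1, 1))
  expect_equal(unname(X[c(2, 3), 1]), c(0, 0))

  # independent finite-difference-in-the-field check of the same entry:
  # difference quotient of the flow at th and th + h, exact in GF(p)
  h <- 1e6
  base <- sio_output_series(m, list(x = 1, th = 1), order = 3)
  pert <- sio_output_series(m, list(x = 1, th = 1 + h), order = 3)
  fd1 <- ((pert[1, 2] - base[1, 2]) %% p_mod * inv(h)) %% p_mod
  # t-coefficient of x(t) is th*x0: exactly linear in th, so the exact
  # difference quotient equals the derivative
  expect_equal(unname(fd1), unname(X[2, 2]))
})

test_that("the output Jacobian has the Kalman row space on linear models", {
  for (i in 1:5) {
    fx <- random_linear_fixture(sample(2:6, 1), 1, seed = 400 + i)
    vs <- variational_system(fx$model)
    ss <- specialize(vs, seed = 500 + i)
    sol <- series_solve(ss)
    jac <- output_jacobian(ss, sol)
    expect_identical(ncol(jac), nrow(fx$A))
    expect_identical(odesio:::cpp_mod_rank(jac, p_mod), fx$truth$rank)
    expect_identical(transcendence_degree(jac),
                     as.integer(nrow(fx$A) - fx$truth$rank))
  }
})

test_that("transcendence degree zero certifies FISPO and locates SU sets", {
  expect_identical(transcendence_degree(structure(diag(5), prime = p_mod)),
                   0L)

  res <- sio_algebraic(clv_model(2), output_config("pi1", "pi1"), seed = 3)
  expect_false(res$fispo)
  expect_identical(res$evidence$transcendence_degree, 1L)
  expect_setequal(names(which(res$parameter_status == "SU")),
                  c("g1", "A11", "A12"))
  expect_identical(res$state_status[["pi1"]], "observable")

  res_pc <- sio_algebraic(pc_model(),
                          output_config("S,R,PS,PR",
                                        c("S", "R", "PS", "PR")),
                          seed = 3)
  expect_setequal(names(which(res_pc$parameter_status == "SU")),
                  c("eps", "KI"))
  expect_identical(res_pc$state_status[["I"]], "unobservable")
  expect_setequal(names(which(res_pc$state_status == "observable")),
                  c("S", "R", "PS", "PR"))
})

test_that("transcendence degree is seed-invariant", {
  for (model in list(glv_model(2), clv_model(3), qsmi_model(2, 1))) {
    degs <- vapply(c(11L, 22L, 33L), function(s)
      sio_algebraic(model, seed = s)$evidence$transcendence_degree,
      integer(1))
    expect_length(unique(degs), 1L)
  }
})

test_that("engines return identical classifications on small zoo models", {
  cases <- list(
    list(glv_model(2), NULL),
    list(glv_model(2), output_config("x2", "x2")),
    list(clv_model(2), NULL),
    list(clv_model(2, input = TRUE), NULL),
    list(qsmi_model(2, 1), output_config("x1,m1", c("x1", "m1"))))
  for (cs in cases) {
    pair <- sio(cs[[1]], outputs = cs[[2]], engine = "both", seed = 17)
    expect_true(pair$agree)
  }
})
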