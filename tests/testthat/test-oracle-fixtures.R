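# Ground-truth oracles: Kalman observability, random linear fixtures and
# symmetry-constructed nonlinear fixtures.

test_that("Kalman observability handles the canonical textbook cases", {
  # double integrator measured at position: fully observable
  A <- matrix(c(0, 0, 1, 0), 2, 2)   # column-major: x1' = x2
  k1 <- kalman_observability(A, matrix(c(1, 0), 1))
  expect_identical(k1$rank, 2L)
  expect_identical(unname(k1$state_status), c("observable", "observable"))

  # measured at velocity: the position is invisible
  k2 <- kalman_observability(A, matrix(c(0, 1), 1))
  expect_identical(k2$rank, 1L)
  expect_identical(k2$state_status[["x1"]], "unobservable")
  expect_identical(k2$state_status[["x2"]], "observable")

  # full measurement: rank n
  k3 <- kalman_observability(matrix(sample(-3:3, 16, TRUE), 4), diag(4))
  expect_identical(k3$rank, 4L)
  expect_true(all(k3$state_status == "observable"))

  expect_error(kalman_observability(matrix(0, 2, 3), diag(2)),
               class = "odesio_dimension_mismatch")
})

test_that("random fixtures are seed-reproducible and respect sparsity", {
  f1 <- random_linear_fixture(5, 2, seed = 77)
  f2 <- random_linear_fixture(5, 2, seed = 77)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$C, f2$C)
  expect_identical(serialize_sio_model(f1$model),
                   serialize_sio_model(f2$model))

  # sparsity 1: A is zero, only the measured state is observable
  f0 <- random_linear_fixture(3, 1, seed = 5, sparsity = 1)
  expect_true(all(f0$A == 0))
  expect_identical(f0$truth$rank, 1L)
  expect_identical(sum(f0$truth$state_status == "observable"), 1L)

  expect_error(random_linear_fixture(9, 1), class = "odesio_dimension_mismatch")
  expect_error(random_linear_fixture(4, 5), class = "odesio_dimension_mismatch")
})

test_that("symmetry fixtures are classified exactly as constructed", {
  for (kind in c("product", "state_scaling")) {
    fx <- symmetry_fixture(kind)
    for (eng in c("lie", "algebraic")) {
      res <- sio(fx$model, engine = eng, seed = 13)
      expect_setequal(names(which(res$parameter_status == "SU")), fx$su)
      expect_setequal(names(which(res$state_status == "unobservable")),
                      fx$unobservable)
    }
  }
  # the product fixture loses exactly one rank: n + p - 1 = 2
  expect_identical(sio(symmetry_fixture("product")$model, seed = 13)$rank, 2L)
  expect_error(symmetry_fixture("rotation"), class = "odesio_unknown_kind")
})

test_that("applying the symmetry leaves the output series unchanged", {
  # state_scaling: x2 -> c x2, b12 -> b12/c, b22 -> b22/c with c = 2
  fx <- symmetry_fixture("state_scaling")
  vals <- list(x1 = 7, x2 = 11, r1 = 5, r2 = 13, b11 = 3, b12 = 6,
               b21 = 9, b22 = 10)
  base <- sio_output_series(fx$model, vals, order = 10)
  trans <- sio_output_series(fx$model, fx$transform(vals, 2), order = 10)
  expect_identical(base, trans)

  # a transformation that is NOT a symmetry changes the series
  vals2 <- vals; vals2$b11 <- vals2$b11 + 1
  expect_false(identical(base, sio_output_series(fx$model, vals2,
                                                 order = 10)))

  # product fixture: th1 -> 2 th1, th2 -> th2/2
  fp <- symmetry_fixture("product")
  vp <- list(x = 3, th1 = 5, th2 = 8)
  expect_identical(sio_output_series(fp$model, vp, order = 8),
                   sio_output_series(fp$model, fp$transform(vp, 2),
                                     order = 8))
})

test_that("oracle code does not call into the engines", {
  engine_fns <- c("sio", "sio_lie", "sio_algebraic", "oi_matrix",
                  "generic_rank", "lie_derivative", "variational_system",
                  "specialize", "series_solve", "output_jacobian",
                  "transcendence_degree")
  for (fn in c("kalman_observability", "random_linear_fixture",
               "symmetry_fixture")) {
    globals <- codetools::findGlobals(get(fn, envir = asNamespace("odesio")))
    expect_length(intersect(globals, engine_fns), 0)
  }
})
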