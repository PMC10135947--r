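test_that("model construction validates symbols and dimensions", {
  m <- ode_model("x", dynamics = "-x", outputs = "x")
  expect_s3_class(m, "ode_model")
  expect_identical(m$states, "x")
  expect_length(m$parameters, 0)

  g <- glv_model(2)
  expect_identical(g$states, c("x1", "x2"))
  expect_identical(g$parameters, c("r1", "r2", "b11", "b12", "b21", "b22"))

  expect_error(ode_model("x", parameters = "th", dynamics = "th*z",
                         outputs = "x"),
               class = "odesio_unknown_symbol")
  expect_error(ode_model(c("x", "y"), dynamics = "-x", outputs = "x"),
               class = "odesio_dimension_mismatch")
  expect_error(ode_model(c("x", "x"), dynamics = list("-x", "x"),
                         outputs = "x"),
               class = "odesio_invalid_expression")
  expect_error(ode_model("x", dynamics = "sin(x)", outputs = "x"),
               class = "odesio_invalid_expression")
})

test_that("augmentation appends parameters with zero dynamics", {
  aug <- augment(glv_model(2))
  expect_length(aug$aug_states, 8)
  expect_identical(aug$aug_states[1:2], c("x1", "x2"))
  expect_true(all(vapply(aug$aug_dynamics[3:8], function(e)
    identical(e, 0), logical(1))))

  m <- ode_model("x", dynamics = "-x", outputs = "x")
  expect_length(augment(m)$aug_states, 1)

  # the phage cocktail model: 5 states + 13 unknowns, dosing rates known
  aug_pc <- augment(pc_model())
  expect_length(aug_pc$aug_states, 18)

  # augmenting the augmented model (as a parameter-free model) adds nothing
  flat <- as_ode_model(aug)
  expect_length(augment(flat)$aug_states, 8)
  expect_length(flat$parameters, 0)
})

test_that("output configurations replace outputs without touching the model", {
  g <- glv_model(2)
  g1 <- with_outputs(g, output_config("x1", "x1"))
  expect_length(g1$outputs, 1)
  expect_length(g$outputs, 2)     # original untouched

  rm <- with_outputs(g, output_config("RM", c("x1/(x1+x2)", "x2/(x1+x2)")))
  expect_length(rm$outputs, 2)
  expect_setequal(all.vars(rm$outputs[[1]]), c("x1", "x2"))

  expect_error(with_outputs(g, output_config("bad", "x3")),
               class = "odesio_unknown_symbol")
  expect_error(with_outputs(g, output_config("bad", "r1")),
               class = "odesio_unknown_symbol")
  expect_error(output_config("empty", character()),
               class = "odesio_dimension_mismatch")
})

test_that("the documented example file parses to the 2-species gLV model", {
  txt <- c("model glv2",
           "states x1 x2",
           "params r1 r2 b11 b12 b21 b22",
           "# a comment",
           "ode x1 = r1*x1 + b11*x1*x1 + b12*x1*x2",
           "ode x2 = r2*x2 + b21*x1*x2 + b22*x2*x2",
           "out y1 = x1",
           "out y2 = x2")
  m <- parse_sio_model(txt)
  g <- glv_model(2)
  expect_identical(m$states, g$states)
  expect_setequal(m$parameters, g$parameters)
  for (i in 1:2)
    expect_true(expr_equal(m$dynamics[[i]], g$dynamics[[i]]))
})

test_that("parse errors carry line numbers and classes", {
  expect_error(parse_sio_model(""), class = "odesio_parse_error")
  expect_error(parse_sio_model(c("model m", "states x", "ode x = r1*(x",
                                 "out y = x")),
               regexp = "line 3")
  expect_error(parse_sio_model(c("model m", "states x", "frobnicate q")),
               regexp = "line 3")
  expect_error(parse_sio_model(c("model m", "states x", "out y = x")),
               regexp = "missing ode")
})

test_that("serialization round-trips every zoo model symbolically", {
  zoo <- list(glv_model(2), glv_model(3), clv_model(2), clv_model(3, TRUE),
              qsmi_model(2, 1), qsmi_model(2, 2), msmi_model(2, 1),
              msmi_model(2, 2, reading = "classic"), pc_model(),
              pc_model(scaled = TRUE))
  for (m in zoo) {
    m2 <- parse_sio_model(serialize_sio_model(m))
    expect_identical(m2$states, m$states)
    expect_identical(sort(m2$parameters), sort(m$parameters))
    expect_identical(m2$inputs, m$inputs)
    expect_identical(m2$input_derivatives, m$input_derivatives)
    expect_setequal(as.character(names(m2$known_constants)),
                    as.character(names(m$known_constants)))
    for (i in seq_along(m$states))
      expect_true(expr_equal(m2$dynamics[[i]], m$dynamics[[i]]))
    for (j in seq_along(m$outputs))
      expect_true(expr_equal(m2$outputs[[j]], m$outputs[[j]]))
  }
})

test_that("model files survive a write/read cycle including metadata", {
  m <- ode_model("x", inputs = "u", dynamics = "u*x - x", outputs = "x",
                 known_constants = list(c0 = "4/10"),
                 input_derivatives = 5L, name = "io")
  path <- withr::local_tempfile(fileext = ".model")
  write_sio_model(m, path)
  m2 <- read_sio_model(path)
  expect_identical(m2$input_derivatives, c(u = 5L))
  expect_true(expr_equal(m2$known_constants$c0, quote(4 / 10)))
  expect_true(expr_equal(m2$dynamics[[1]], m$dynamics[[1]]))
})
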