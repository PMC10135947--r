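# Model zoo: family constructors, configuration enumeration and the
# encoded expectations.

test_that("gLV constructor produces the stated dimensions", {
  g2 <- glv_model(2)
  expect_length(g2$states, 2)
  expect_length(g2$parameters, 6)
  g3 <- glv_model(3)
  expect_length(g3$parameters, 12)
  expect_true(all(c("b12", "b21") %in% g3$parameters))  # not symmetric
  expect_error(glv_model(0), class = "odesio_dimension_mismatch")
})

test_that("cLV reduction eliminates the last relative abundance", {
  c2 <- clv_model(2)
  expect_identical(c2$states, "pi1")
  expect_setequal(c2$parameters, c("g1", "A11", "A12"))
  # with n = 2 the reduced dynamics collapse to pi1 * F1 * (1 - pi1)
  F1 <- quote(g1 + A11 * pi1 + A12 * (1 - pi1))
  expect_true(expr_equal(c2$dynamics[[1]],
                         bquote(pi1 * .(F1) * (1 - pi1))))

  c3u <- clv_model(3, input = TRUE)
  expect_identical(c3u$states, c("pi1", "pi2"))
  expect_setequal(grep("^B", c3u$parameters, value = TRUE), c("B11", "B21"))
  expect_identical(c3u$inputs, "u1")
  expect_true(is.na(c3u$input_derivatives[["u1"]]))  # generic smooth input
  expect_error(clv_model(1), class = "odesio_dimension_mismatch")
})

test_that("QSMI parameter families have the right cardinalities", {
  q21 <- qsmi_model(2, 1)
  expect_length(q21$states, 3)
  expect_length(q21$parameters, 10)   # 2+2+2+1+1+2
  q22 <- qsmi_model(2, 2)
  expect_length(q22$states, 4)
  expect_length(grep("^phi", q22$parameters), 8)

  # consumption k_ij and diagonal by-product phi_ijj contribute the same
  # monomial to dm_j/dt: shifting c from one to the other leaves the
  # dynamics invariant
  dm1 <- q21$dynamics[[3]]
  shifted <- odesio:::subst_symbols(dm1, list(
    k21 = quote(k21 + 5), phi211 = quote(phi211 + 5)))
  expect_true(expr_equal(dm1, shifted))
})

test_that("MSMI readings produce the documented families", {
  m21 <- msmi_model(2, 1)
  expect_length(m21$states, 3)
  fam <- function(model, stem)
    length(grep(paste0("^", stem, "[0-9]"), model$parameters))
  expect_identical(vapply(c("V", "K", "d", "Vs", "Ks", "ds", "f", "phi"),
                          fam, integer(1), model = m21),
                   c(V = 2L, K = 2L, d = 2L, Vs = 2L, Ks = 2L, ds = 1L,
                     f = 1L, phi = 2L))
  m22 <- msmi_model(2, 2)
  expect_length(grep("^phi", m22$parameters), 8)

  # independent by-product constants add a Kb family
  m_ind <- msmi_model(2, 1, shared_byproduct_K = FALSE)
  expect_length(grep("^Kb", m_ind$parameters), 2)

  # classic-Monod reading builds a valid, different model
  m_cl <- msmi_model(2, 1, reading = "classic")
  expect_false(expr_equal(m_cl$dynamics[[3]], m21$dynamics[[3]],
                          vars = union(all.vars(m_cl$dynamics[[3]]),
                                       all.vars(m21$dynamics[[3]]))))
})

test_that("PC models carry the documented unknowns and known constants", {
  pc <- pc_model()
  expect_identical(pc$states, c("S", "R", "PS", "I", "PR"))
  expect_length(pc$parameters, 13)
  expect_setequal(names(pc$known_constants), c("rhoS", "rhoR"))
  expect_length(augment(pc)$aug_states, 18)

  ps <- pc_model(scaled = TRUE)
  expect_length(ps$parameters, 12)
  expect_identical(ps$inputs, c("u1", "u2"))
  expect_length(augment(ps)$aug_states, 17)
})

test_that("configuration enumeration expands the table shorthand", {
  cfg_glv2 <- enumerate_configs("glv", n = 2)
  expect_length(cfg_glv2, 4)   # (x1,x2), (x1), (x2), RM
  expect_setequal(vapply(cfg_glv2, `[[`, "", "label"),
                  c("x1,x2", "x1", "x2", "RM"))

  expect_length(enumerate_configs("glv", n = 3), 8)
  expect_length(enumerate_configs("pc", scaled = FALSE), 5)
  expect_length(enumerate_configs("pc", scaled = TRUE), 11)
  expect_length(enumerate_configs("qsmi", n = 2, nm = 2), 15)
  expect_error(enumerate_configs("nope"), class = "odesio_unknown_kind")
})

test_that("the shipped expectations file matches its generator", {
  for (tab in 1:5) {
    shipped <- zoo_expectations(tab)
    rebuilt <- zoo_expectations(tab, regenerate = TRUE)
    expect_identical(shipped, rebuilt)
  }
  expect_error(zoo_expectations(9), class = "odesio_unknown_table")
})

test_that("every expectation row partitions its model's symbol sets", {
  for (tab in 1:5) {
    df <- zoo_expectations(tab)
    expect_identical(odesio:::validate_expectations(df), character(0))
  }
})

test_that("the zoo covers more than one hundred concrete analyses", {
  n_total <- sum(vapply(1:5, function(t) nrow(zoo_expectations(t)),
                        integer(1)))
  expect_gt(n_total, 100)
})

test_that("species relabelling maps single-species classifications onto each other", {
  relabel <- c(x1 = "x2", x2 = "x1", r1 = "r2", r2 = "r1",
               b11 = "b22", b12 = "b21", b21 = "b12", b22 = "b11")
  r1 <- sio(glv_model(2), outputs = "x1", seed = 9)
  r2 <- sio(glv_model(2), outputs = "x2", seed = 9)
  mapped <- r1$parameter_status
  names(mapped) <- unname(relabel[names(mapped)])
  expect_identical(mapped[names(r2$parameter_status)], r2$parameter_status)
  expect_identical(unname(r1$state_status[c("x1", "x2")]),
                   unname(r2$state_status[c("x2", "x1")]))

  # QSMI: swapping the two species maps (x1) onto (x2)
  q1 <- sio(qsmi_model(2, 1), outputs = "x1", seed = 9)
  q2 <- sio(qsmi_model(2, 1), outputs = "x2", seed = 9)
  mapped_q <- q1$parameter_status
  names(mapped_q) <- vapply(names(mapped_q), function(nm) {
    # swap the species index (first digit after the stem); families indexed
    # by metabolite only (ds, f) keep their names
    stem <- sub("[0-9].*$", "", nm)
    if (stem %in% c("ds", "f")) return(nm)
    idx <- sub("^[A-Za-z]+", "", nm)
    first <- chartr("12", "21", substr(idx, 1, 1))
    paste0(stem, first, substr(idx, 2, nchar(idx)))
  }, "")
  # ds1/f1 keep their names (metabolite-indexed)
  expect_identical(sort(names(which(mapped_q == "SLI"))),
                   sort(names(which(q2$parameter_status == "SLI"))))
})
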