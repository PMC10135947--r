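# Encoded expected classifications
#
# The reference classification tables (one per model family) are written in
# a compact shorthand: a starred subscript means "all indexes", and rows
# indexed by i, j, k (i != j != k) stand for every concrete instantiation.
# The functions below expand that shorthand into one row per concrete
# (model, dimensions, measurement configuration) analysis; the expanded
# table is also shipped as a versioned structured-text file under
# inst/extdata/ and the two are checked against each other in the tests.

sort_c <- function(x) sort(x, method = "radix")  # locale-independent

exp_row <- function(table, family, n = NA_integer_, nm = NA_integer_,
                    input = FALSE, scaled = FALSE, config, outputs,
                    id, nonid, obs, nonobs) {
  list(table = table, family = family, n = n, nm = nm, input = input,
       scaled = scaled, config = config, outputs = outputs,
       id = sort_c(id), nonid = sort_c(nonid), obs = sort_c(obs),
       nonobs = sort_c(nonobs))
}

subsets_measured <- function(n, include_empty = FALSE) {
  # all species, then (for n = 3) pairs, then singletons, then optionally none
  out <- list(seq_len(n))
  if (n >= 3) out <- c(out, lapply(utils::combn(n, n - 1L, simplify = FALSE),
                                   identity))
  out <- c(out, as.list(seq_len(n)))
  if (include_empty) out <- c(out, list(integer(0)))
  out
}

expectations_glv <- function() {
  rows <- list()
  for (n in 2:3) {
    m <- glv_model(n)
    states <- m$states
    r <- paste0("r", seq_len(n))
    b_all <- grep("^b", m$parameters, value = TRUE)
    bcol <- function(j) paste0("b", seq_len(n), j)
    add <- function(...) rows[[length(rows) + 1L]] <<- exp_row(...)
    add(1L, "glv", n = n, config = paste(states, collapse = ","),
        outputs = states, id = m$parameters, nonid = character(),
        obs = states, nonobs = character())
    for (meas in subsets_measured(n)[-1]) {
      unmeas <- setdiff(seq_len(n), meas)
      add(1L, "glv", n = n,
          config = paste(states[meas], collapse = ","),
          outputs = states[meas],
          id = c(r, unlist(lapply(meas, bcol))),
          nonid = unlist(lapply(unmeas, bcol)),
          obs = states[meas], nonobs = states[unmeas])
    }
    total <- paste(states, collapse = " + ")
    add(1L, "glv", n = n, config = "RM",
        outputs = sprintf("x%d/(%s)", seq_len(n), total),
        id = r, nonid = b_all, obs = character(), nonobs = states)
  }
  rows
}

expectations_clv <- function() {
  rows <- list()
  for (n in 2:3) {
    for (input in c(FALSE, TRUE)) {
      m <- clv_model(n, input = input)
      states <- m$states
      gA <- grep("^(g|A)", m$parameters, value = TRUE)
      B <- grep("^B", m$parameters, value = TRUE)
      configs <- if (n == 2) list("pi1")
                 else list(c("pi1", "pi2"), "pi1", "pi2")
      for (meas in configs) {
        rows[[length(rows) + 1L]] <- exp_row(
          2L, "clv", n = n, input = input,
          config = paste(meas, collapse = ","), outputs = meas,
          id = B, nonid = gA, obs = states, nonobs = character())
      }
    }
  }
  rows
}

expectations_qsmi <- function() {
  rows <- list()
  for (dims in list(c(2L, 1L), c(3L, 1L), c(2L, 2L), c(3L, 2L))) {
    n <- dims[1]; nm <- dims[2]
    m <- qsmi_model(n, nm)
    xs <- paste0("x", seq_len(n)); ms <- paste0("m", seq_len(nm))
    dd <- c(paste0("d", seq_len(n)), paste0("ds", seq_len(nm)))
    k_all <- grep("^k", m$parameters, value = TRUE)
    psi_all <- grep("^psi", m$parameters, value = TRUE)
    f_all <- paste0("f", seq_len(nm))
    phi_all <- grep("^phi", m$parameters, value = TRUE)
    add <- function(S, M) {
      if (nm == 2 && length(M) == 2) {
        phi_id <- unlist(lapply(S, function(i)
          c(sprintf("phi%d12", i), sprintf("phi%d21", i))))
        id <- c(dd, f_all, psi_all, phi_id)
      } else if (length(M) == 1) {
        r <- M
        id <- c(dd, paste0("f", r), paste0("psi", seq_len(n), r))
      } else if (length(M) == 0) {
        id <- dd
      } else {  # nm == 1, m measured
        id <- c(dd, f_all, psi_all)
      }
      nonid <- setdiff(m$parameters, id)
      obs <- c(xs[S], ms[M])
      rows[[length(rows) + 1L]] <<- exp_row(
        3L, "qsmi", n = n, nm = nm,
        config = paste(obs, collapse = ","), outputs = obs,
        id = id, nonid = nonid, obs = obs, nonobs = setdiff(c(xs, ms), obs))
    }
    m_levels <- if (nm == 1) list(1L) else list(c(1L, 2L), 1L, 2L)
    for (M in m_levels)
      for (S in subsets_measured(n, include_empty = TRUE)) add(S, M)
    for (S in subsets_measured(n)) add(S, integer(0))
  }
  rows
}

expectations_msmi <- function() {
  rows <- list()
  for (dims in list(c(2L, 1L), c(2L, 2L), c(3L, 2L))) {
    n <- dims[1]; nm <- dims[2]
    m <- msmi_model(n, nm)
    xs <- paste0("x", seq_len(n)); ms <- paste0("m", seq_len(nm))
    dd <- c(paste0("d", seq_len(n)), paste0("ds", seq_len(nm)))
    add <- function(S, M) {
      id <- c(dd,
              paste0("f", M),
              unlist(lapply(S, function(i) paste0("V", i, seq_len(nm)))),
              unlist(lapply(S, function(i) paste0("K", i, M))),
              unlist(lapply(S, function(i) paste0("Ks", i, M))))
      if (nm >= 2 && length(M) > 0) {
        combos <- expand.grid(i = seq_len(n), l = seq_len(nm), j = M)
        combos <- combos[combos$l != combos$j, , drop = FALSE]
        id <- c(id, sprintf("phi%d%d%d", combos$i, combos$l, combos$j))
      }
      id <- intersect(m$parameters, id)
      nonid <- setdiff(m$parameters, id)
      obs <- c(xs[S], ms[M])
      rows[[length(rows) + 1L]] <<- exp_row(
        4L, "msmi", n = n, nm = nm,
        config = paste(obs, collapse = ","), outputs = obs,
        id = id, nonid = nonid, obs = obs, nonobs = setdiff(c(xs, ms), obs))
    }
    m_levels <- if (nm == 1) list(1L) else list(c(1L, 2L), 1L, 2L)
    for (M in m_levels)
      for (S in subsets_measured(n, include_empty = TRUE)) add(S, M)
    for (S in subsets_measured(n)) add(S, integer(0))
  }
  rows
}

expectations_pc <- function() {
  rows <- list()
  orig <- pc_model(scaled = FALSE)
  scal <- pc_model(scaled = TRUE)
  su <- c("eps", "KI")
  add <- function(...) rows[[length(rows) + 1L]] <<- exp_row(...)
  fispo_row <- function(model, outputs, scaled) {
    add(5L, "pc", scaled = scaled, config = paste(outputs, collapse = ","),
        outputs = outputs, id = model$parameters, nonid = character(),
        obs = model$states, nonobs = character())
  }
  fispo_row(orig, "I", scaled = FALSE)
  fispo_row(orig, orig$states, scaled = FALSE)
  for (outputs in list(c("S", "R", "PS", "PR"), c("S", "R"), c("PS", "PR"))) {
    add(5L, "pc", scaled = FALSE, config = paste(outputs, collapse = ","),
        outputs = outputs, id = setdiff(orig$parameters, su), nonid = su,
        obs = c("S", "R", "PS", "PR"), nonobs = "I")
  }
  scaled_configs <- list(
    c("x1", "x2", "x3", "x4", "x5"), c("x1", "x2", "x3", "x5"),
    c("x1", "x2", "x4"), c("x1", "x3", "x4"), c("x2", "x4", "x5"),
    c("x3", "x4", "x5"), c("x1", "x2"), c("x1", "x4"), c("x2", "x4"),
    c("x3", "x5"), "x4")
  for (outputs in scaled_configs) fispo_row(scal, outputs, scaled = TRUE)
  rows
}

build_expectations <- function(table = 1:5) {
  rows <- list()
  if (1L %in% table) rows <- c(rows, expectations_glv())
  if (2L %in% table) rows <- c(rows, expectations_clv())
  if (3L %in% table) rows <- c(rows, expectations_qsmi())
  if (4L %in% table) rows <- c(rows, expectations_msmi())
  if (5L %in% table) rows <- c(rows, expectations_pc())
  rows
}

join_set <- function(x) if (length(x) == 0) "-" else paste(x, collapse = ",")
split_set <- function(s) if (identical(s, "-")) character() else
  strsplit(s, ",", fixed = TRUE)[[1]]

expectations_frame <- function(rows) {
  data.frame(
    table = vapply(rows, `[[`, integer(1), "table"),
    family = vapply(rows, `[[`, character(1), "family"),
    n = vapply(rows, `[[`, integer(1), "n"),
    nm = vapply(rows, `[[`, integer(1), "nm"),
    input = vapply(rows, `[[`, logical(1), "input"),
    scaled = vapply(rows, `[[`, logical(1), "scaled"),
    config = vapply(rows, `[[`, character(1), "config"),
    outputs = vapply(rows, function(r) paste(r$outputs, collapse = ";"), ""),
    id = vapply(rows, function(r) join_set(r$id), ""),
    nonid = vapply(rows, function(r) join_set(r$nonid), ""),
    obs = vapply(rows, function(r) join_set(r$obs), ""),
    nonobs = vapply(rows, function(r) join_set(r$nonobs), ""),
    stringsAsFactors = FALSE)
}

write_expectations_file <- function(path) {
  df <- expectations_frame(build_expectations())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected classifications for the reference tables
#'
#' Returns the encoded expected classification of every concrete
#' (model, dimensions, measurement configuration) analysis of the given
#' reference table: the expected identifiable and non-identifiable
#' parameter sets and observable and non-observable state sets.  By
#' default the rows are read from the versioned data file shipped with the
#' package; `regenerate = TRUE` rebuilds them from the shorthand expansion
#' rules instead (the two are equivalent and tested to match).
#'
#' @param table Table id, 1 to 5 (gLV, cLV, QSMI, MSMI, PC).
#' @param regenerate Rebuild instead of reading the shipped file.
#' @param path Optional alternative expectations file (used by the
#'   self-test's negative control).
#' @return A data frame with one row per concrete configuration; the set
#'   columns (`id`, `nonid`, `obs`, `nonobs`) are comma-joined with `-`
#'   for an empty set, and `outputs` holds the measurement expressions
#'   joined by `;`.
#' @export
zoo_expectations <- function(table, regenerate = FALSE, path = NULL) {
  table <- as.integer(table)
  if (length(table) != 1L || is.na(table) || !table %in% 1:5)
    stop_odesio("unknown_table", "table id must be one of 1..5")
  if (regenerate) {
    df <- expectations_frame(build_expectations(table))
  } else {
    path <- path %||% system.file("extdata", "expectations.tsv",
                                  package = "odesio")
    if (!nzchar(path) || !file.exists(path))
      stop_odesio("parse_error", "expectations file not found")
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df <- df[df$table == table, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

# Build the zoo model that an expectation row refers to.
expectation_model <- function(row, ...) {
  switch(row$family,
         glv = glv_model(row$n),
         clv = clv_model(row$n, input = row$input),
         qsmi = qsmi_model(row$n, row$nm),
         msmi = msmi_model(row$n, row$nm, ...),
         pc = pc_model(scaled = row$scaled),
         stop_odesio("unknown_kind", "unknown family '%s'", row$family))
}

# Check that a set of expectation rows is internally consistent with the
# models it refers to: id/nonid partition the parameter set and obs/nonobs
# partition the state set.  Returns the labels of offending rows.
validate_expectations <- function(df) {
  bad <- character()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    model <- expectation_model(row)
    id <- split_set(row$id); nonid <- split_set(row$nonid)
    obs <- split_set(row$obs); nonobs <- split_set(row$nonobs)
    ok <- setequal(c(id, nonid), model$parameters) &&
      length(intersect(id, nonid)) == 0 &&
      setequal(c(obs, nonobs), model$states) &&
      length(intersect(obs, nonobs)) == 0
    if (!ok)
      bad <- c(bad, sprintf("table %d %s [%s]", row$table, model$name,
                            row$config))
  }
  bad
}

#' Enumerate the measurement configurations of a model family
#'
#' Expands the shorthand of the corresponding reference table into the
#' concrete list of output configurations analysed for the given family
#' and dimensions (e.g. for gLV with n = 2: both states, each single
#' state, and the relative measures RM).
#'
#' @param family `"glv"`, `"clv"`, `"qsmi"`, `"msmi"` or `"pc"`.
#' @param n,nm,input,scaled Model dimensions / variant selectors.
#' @return A list of [output_config()] objects.
#' @export
enumerate_configs <- function(family, n = 2L, nm = 1L, input = FALSE,
                              scaled = FALSE) {
  table <- switch(family, glv = 1L, clv = 2L, qsmi = 3L, msmi = 4L,
                  pc = 5L,
                  stop_odesio("unknown_kind", "unknown family '%s'", family))
  df <- expectations_frame(build_expectations(table))
  keep <- rep(TRUE, nrow(df))
  if (family %in% c("glv", "clv", "qsmi", "msmi")) keep <- keep & df$n == n
  if (family %in% c("qsmi", "msmi")) keep <- keep & df$nm == nm
  if (family == "clv") keep <- keep & df$input == input
  if (family == "pc") keep <- keep & df$scaled == scaled
  df <- df[keep, , drop = FALSE]
  df <- df[!duplicated(df$config), , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i)
    output_config(df$config[i], strsplit(df$outputs[i], ";", fixed = TRUE)[[1]]))
}
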