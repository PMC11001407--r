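# Symbolic expression layer: substitution, series expansion, export,
# limit-safe evaluation.

test_that("substitution replaces symbols and updates the registry", {
  e <- sk_expr(quote(exp(-x)), "x")
  expect_equal(sk_evaluate(sk_substitute(e, list(x = 0)), q = 0), 1)

  f <- sk_expr(quote(beta_A * F_A), c("beta_A", "F_A"))
  deb <- sk_expr(quote(sk_debye(q^2 * Rg2_A)), "Rg2_A")
  g <- sk_substitute(f, list(F_A = deb))
  expect_setequal(g$params, c("beta_A", "Rg2_A"))
  # Debye at x = 1: 2(e^-1 + 1 - 1)/1 = 2/e, against quadrature oracle
  expect_equal(sk_evaluate(g, c(beta_A = 1, Rg2_A = 1), 1),
               debye_quad(1), tolerance = 1e-10)
  expect_error(sk_substitute(f, list(nope = 1)), "nope")
})

test_that("series coefficients in q^2 match Taylor expansions", {
  e <- sk_expr(quote(exp(-q^2 * Rg2)), "Rg2")
  c1 <- series_q2_coefficient(e, 1)
  expect_equal(sk_evaluate(c1, c(Rg2 = 1.7), 0), -1.7)

  d <- sk_expr(quote(sk_debye(q^2 * Rg2)), "Rg2")
  expect_equal(sk_evaluate(series_q2_coefficient(d, 0), c(Rg2 = 2), 0), 1)
  # -Rg2/3, cross-checked by central finite differences of the oracle
  cd <- sk_evaluate(series_q2_coefficient(d, 1), c(Rg2 = 2), 0)
  h <- 1e-5
  fd <- (debye_quad(2 * h) - debye_quad(0)) / h   # d/d(q^2) at 0, Rg2 = 2
  expect_equal(cd, fd, tolerance = 1e-4)
  expect_equal(cd, -2 / 3, tolerance = 1e-12)
})

test_that("removable singularities expand correctly (explicit division)", {
  # Debye written out by hand: the x^2 denominator shares zeros with the
  # numerator and the expansion must shift through them
  d <- sk_expr(quote(2 * (exp(-q^2 * Rg2) + q^2 * Rg2 - 1) / (q^2 * Rg2)^2),
               "Rg2")
  expect_equal(sk_evaluate(series_q2_coefficient(d, 0), c(Rg2 = 1), 0), 1)
  expect_equal(sk_evaluate(series_q2_coefficient(d, 1), c(Rg2 = 3), 0), -1,
               tolerance = 1e-12)
  # a genuine pole must error
  p <- sk_expr(quote(1 / (q^2 * Rg2)), "Rg2")
  expect_error(series_q2_coefficient(p, 1), "analytic|singular")
})

test_that("export dialects follow their power conventions", {
  expect_identical(sk_export(sk_expr(quote(x^2), "x"), "python"), "x**2")
  expect_match(sk_export(sk_expr(quote(x^1.5), "x"), "csrc"), "pow(",
               fixed = TRUE)
  # small integer powers are expanded into products in C
  expect_false(grepl("pow", sk_export(sk_expr(quote(x^2), "x"), "csrc")))
  expect_identical(sk_export(sk_expr(1), "latex"), "1")
  expect_match(sk_export(sk_expr(quote(x^2), "x"), "dflt"), "\\^")
})

test_that("python export of closed-form factors round-trips numerically", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(101)
  facs <- list(
    subunit_factor("GaussianPolymer", "F", tag = "p"),
    subunit_factor("GaussianPolymer", "A", "end1", tag = "p"),
    subunit_factor("GaussianLoop", "F", tag = "p"),
    subunit_factor("ThinRod", "F", tag = "r"),
    subunit_factor("ThinCircle", "F", tag = "c"),
    subunit_factor("SolidSphere", "F", tag = "s"),
    subunit_factor("ThinDisk", "F", tag = "d"),
    subunit_factor("SolidSphericalShell", "A", "center", tag = "h"))
  params <- c(Rg2_p = 1.3, L_r = 2.7, R_c = 1.9, R_s = 1.1, R_d = 2.2,
              Ri_h = 0.8, Ro_h = 1.6)
  qv <- sort(runif(10, 0.05, 6))
  lines <- c(sk_python_preamble(), "import json",
             paste0(names(params), " = ", params),
             sprintf("q = np.array([%s])",
                     paste(format(qv, digits = 17), collapse = ",")))
  vals <- lapply(facs, sk_evaluate, params = params, q = qv)
  for (i in seq_along(facs))
    lines <- c(lines, sprintf("v%d = %s", i, sk_export(facs[[i]], "python")))
  lines <- c(lines, sprintf("print(json.dumps([%s]))",
                            paste(sprintf("list(v%d)", seq_along(facs)),
                                  collapse = ",")))
  py <- tempfile(fileext = ".py")
  writeLines(lines, py)
  out <- system2("python", py, stdout = TRUE)
  pv <- do.call(rbind, jsonlite::fromJSON(out, simplifyVector = FALSE) |>
                  lapply(unlist))
  for (i in seq_along(facs))
    expect_lt(max(abs(pv[i, ] - vals[[i]]) / pmax(abs(vals[[i]]), 1e-12)),
              1e-10)
})

test_that("evaluation is limit-safe at q = 0 and errors on unbound symbols", {
  for (f in list(subunit_factor("GaussianPolymer", "F", tag = "p"),
                 subunit_factor("ThinRod", "F", tag = "p"),
                 subunit_factor("GaussianLoop", "F", tag = "p"))) {
    params <- setNames(rep(1.5, length(f$params)), f$params)
    expect_equal(sk_evaluate(f, params, 0)[1], 1, tolerance = 1e-12)
  }
  d <- sk_expr(quote(sk_debye(q^2 * Rg2_p) * beta_p), c("Rg2_p", "beta_p"))
  expect_error(sk_evaluate(d, c(Rg2_p = 1), 1), "beta_p")
})

test_that("no automatic simplification, but the explicit pass folds", {
  e <- sk_expr(quote(1 * x + 0), "x")   # stored verbatim
  expect_identical(deparse(e$expr), "1 * x + 0")
  s <- sk_simplify(e)
  expect_identical(deparse(s$expr), "x")
  expect_identical(sk_simplify(sk_expr(quote(2 + 3)))$expr, 5)
})
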