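# Composite assembly: pair terms, form factors, amplitudes, phase factors,
# term bookkeeping, hierarchy recursion.

test_that("pair terms follow the path rules", {
  # directly linked units: product of two amplitudes, no phase factor
  w <- sk_world()
  add_unit(w, "GaussianPolymer", "A")
  link_unit(w, "GaussianPolymer", "C.end1", "A.end2")
  t <- pair_term(w, "A", "C")
  txt <- paste(deparse(t$expr), collapse = "")
  expect_match(txt, "beta_A")
  expect_match(txt, "beta_C")
  expect_equal(sk_evaluate(t, c(beta_A = 2, beta_C = 3, Rg2_A = 1,
                                Rg2_C = 1), 0)[1], 6)
  # indirectly connected through A: amplitude, phase factor, amplitude
  link_unit(w, "GaussianPolymer", "B.end1", "A.end1")
  t2 <- pair_term(w, "B", "C")
  # B and C sit at opposite ends of A: the bridge is A's end1-end2 phase
  # factor exp(-x_A)
  v <- sk_evaluate(t2, c(beta_B = 1, beta_C = 1, Rg2_A = 1, Rg2_B = 1,
                         Rg2_C = 1), 1)
  aend <- end_amp_quad(1)
  expect_equal(v, aend * exp(-1) * aend, tolerance = 1e-10)
  expect_error(pair_term(w, "A", "A"), "form factor term")
  w2 <- sk_world(); add_unit(w2, "GaussianPolymer", "Z")
  expect_error(pair_term(w, "A", "Z"), "unknown unit|not connected")
})

test_that("single sub-unit form factors reduce to their table entry", {
  w <- sk_world()
  add_unit(w, "GaussianPolymer", "P", tag = "p")
  f <- form_factor(w, "P")
  expect_equal(sk_evaluate(f, std_params, c(0.5, 1, 2)),
               debye_quad(c(0.25, 1, 4)), tolerance = 1e-10)
})

test_that("N equal end-linked polymers scatter as one long chain", {
  # exact identity: the composite F equals the Debye function evaluated at
  # N q^2 Rg2 (checked at random parameter points, tight tolerance)
  set.seed(5)
  for (N in c(2, 3, 10)) {
    ch <- build_chain(n = N, name = sprintf("C%d", N))
    f <- form_factor(ch$world, ch$name)
    for (rep in 1:3) {
      Rg2 <- runif(1, 0.5, 2)
      qv <- runif(5, 0.05, 3)
      expect_equal(sk_evaluate(f, c(Rg2_p = Rg2, beta_p = 1), qv),
                   debye_quad(N * qv^2 * Rg2), tolerance = 1e-9,
                   label = sprintf("N = %d", N))
    }
  }
})

test_that("generic micelle equation has the diagrammatic term multiset", {
  m <- build_micelle()
  fg <- FormFactorGeneric(m$world, m$name)
  info <- attr(fg, "terms")
  kinds <- vapply(info, `[[`, "", "kind")
  expect_identical(sum(kinds == "form"), 4L)            # F_s + 3 F_p
  expect_identical(attr(fg, "n_interference_terms"), 12L)
  # classify pair terms: sphere-polymer (6 of 12) vs polymer-polymer (6)
  pairs <- info[kinds == "pair"]
  sp <- vapply(pairs, function(x) x$I == "core" || x$J == "core", logical(1))
  expect_identical(sum(vapply(pairs[sp], `[[`, 1L, "mult")), 6L)
  expect_identical(sum(vapply(pairs[!sp], `[[`, 1L, "mult")), 6L)
  # the abstract symbols are exactly the diagram's factors
  expect_setequal(fg$params,
                  c("beta_s", "beta_p", "F_s", "F_p", "A_s_surface",
                    "A_p_end1", "Psi_s_surface_surface"))
})

test_that("term count is n + n(n-1) for an n-unit tree", {
  for (n in c(2L, 5L, 9L)) {
    ch <- build_chain(n = n, name = sprintf("T%d", n))
    f <- form_factor(ch$world, ch$name)
    expect_identical(attr(f, "n_form_terms"), n)
    expect_identical(attr(f, "n_interference_terms"), as.integer(n * (n - 1)))
  }
})

test_that("composite amplitudes follow the generic sum", {
  d <- build_diblock()
  amp <- form_factor_amplitude(d$world, "DiBlockCopolymer:A.end1")
  # (beta_A A_end(x_A) + beta_B Psi_A,end1,end2 A_end(x_B)) / (beta_A+beta_B)
  p <- c(Rg2_A = 1, Rg2_B = 2, beta_A = 1, beta_B = 0.5)
  qv <- c(0.3, 1, 2)
  expected <- (1 * end_amp_quad(qv^2) +
               0.5 * exp(-qv^2) * end_amp_quad(2 * qv^2)) / 1.5
  expect_equal(sk_evaluate(amp, p, qv), expected, tolerance = 1e-10)
  expect_equal(sk_evaluate(amp, p, 0)[1], 1)   # normalized
  expect_error(form_factor_amplitude(d$world, "DiBlockCopolymer:A.end9"),
               "end9")
})

test_that("phase factors multiply along the unique path", {
  w <- sk_world()
  add_unit(w, "GaussianPolymer", "A")
  link_unit(w, "GaussianPolymer", "B.end1", "A.end2")
  # same realized point (two addresses of the co-located link)
  expect_identical(phase_factor(w, "A.end2", "B.end1")$expr, 1)
  p1 <- phase_factor(w, "A.end1", "A.end2")
  expect_equal(sk_evaluate(p1, c(Rg2_A = 1), 2), exp(-4), tolerance = 1e-12)
  p2 <- phase_factor(w, "A.end1", "B.end2")
  expect_equal(sk_evaluate(p2, c(Rg2_A = 1, Rg2_B = 2), 1),
               exp(-1) * exp(-2), tolerance = 1e-12)
  expect_false(any(grepl("beta", p2$params)))   # no contrasts in Psi
  add_unit(w, "GaussianPolymer", "Z")   # a second, disconnected graph
  expect_error(phase_factor(w, "A.end1", "Z.end1"), "different structures")
})

test_that("normalization fixes F(0) = A(0) = Psi(0) = 1; zero contrast errors", {
  sc <- build_star_chain()
  p <- c(Rg2_pA = 1, Rg2_pB = 2, beta_pA = 0.3, beta_pB = 1.2)
  expect_equal(sk_evaluate(form_factor(sc$world, "chain"), p, 0)[1], 1,
               tolerance = 1e-12)
  expect_equal(sk_evaluate(form_factor_amplitude(
    sc$world, "chain:star3:diblock1:polyA.end1"), p, 0)[1], 1,
    tolerance = 1e-12)
  expect_equal(sk_evaluate(phase_factor(
    sc$world, "chain:star1:diblock1:polyB.end2",
    "chain:star5:diblock3:polyB.end2"), p, 0)[1], 1, tolerance = 1e-12)
  # a lone Point cannot be normalized
  w <- sk_world(); add_unit(w, "Point", "pt")
  expect_error(form_factor(w, "pt"), "zero")
})

test_that("unnormalized output omits only the contrast denominator", {
  d <- build_diblock()
  p <- c(Rg2_A = 1, Rg2_B = 1, beta_A = 2, beta_B = 1)
  qv <- c(0, 0.7, 1.5)
  fu <- form_factor(d$world, d$name, normalized = FALSE)
  fn <- form_factor(d$world, d$name)
  expect_equal(sk_evaluate(fu, p, qv), 9 * sk_evaluate(fn, p, qv),
               tolerance = 1e-12)
})

test_that("composite F stays non-negative on a dense grid for all fixtures", {
  g <- as.numeric(make_q_grid(0.01, 50, 400))
  cases <- list(
    list(build_diblock(), c(Rg2_A = 1, Rg2_B = 2, beta_A = 1, beta_B = -0.5)),
    list(build_micelle(), c(R_s = 3, Rg2_p = 1, beta_s = 1, beta_p = 1)),
    list(build_decorated_polymer(),
         c(R_s = 1, Rg2_p = 2, beta_s = 1, beta_p = 0.2)),
    list(build_star_chain(),
         c(Rg2_pA = 1, Rg2_pB = 1, beta_pA = 0, beta_pB = 1)))
  for (cs in cases) {
    nm <- if (!is.null(cs[[1]]$name)) cs[[1]]$name else cs[[1]]$chain
    v <- sk_evaluate(form_factor(cs[[1]]$world, nm), cs[[2]], g)
    expect_gte(min(v), -1e-12)
  }
})

test_that("hierarchical derivation equals the flat construction", {
  sc <- build_star_chain()
  p <- c(Rg2_pA = 1, Rg2_pB = 1.5, beta_pA = 1, beta_pB = 0.7)
  qv <- exp(seq(log(0.02), log(20), length.out = 20))
  vh <- sk_evaluate(form_factor(sc$world, sc$chain), p, qv)
  fl <- build_star_chain_flat()
  vf <- sk_evaluate(form_factor(fl$world, fl$name), p, qv)
  expect_lt(max(abs(vh - vf)), 1e-9)
})
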