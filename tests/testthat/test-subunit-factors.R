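# The sub-unit factor table: every closed form is checked against the
# pair-distance Monte Carlo oracle, plus the structural identities the
# defining averages imply.

test_that("all Tier-1 factors are normalized and curve downward at small q", {
  cases <- list(
    list("GaussianPolymer", list(c("F"), c("A", "end1"), c("A", "middle"),
                                 c("A", "contour"), c("Psi", "end1", "end2"),
                                 c("Psi", "end1", "middle"),
                                 c("Psi", "end1", "contour"),
                                 c("Psi", "middle", "contour"),
                                 c("Psi", "contour", "contour"))),
    list("GaussianLoop", list(c("F"), c("A", "contour"),
                              c("Psi", "contour", "contour"))),
    list("ThinRod", list(c("F"), c("A", "end1"), c("A", "middle"),
                         c("A", "contour"), c("Psi", "end1", "end2"),
                         c("Psi", "end2", "middle"),
                         c("Psi", "end1", "contour"),
                         c("Psi", "contour", "contour"))),
    list("ThinCircle", list(c("F"), c("A", "center"), c("A", "contour"),
                            c("Psi", "center", "contour"))),
    list("SolidSphere", list(c("F"), c("A", "center"), c("A", "surface"),
                             c("Psi", "center", "surface"),
                             c("Psi", "surface", "surface"))),
    list("ThinSphericalShell", list(c("F"), c("A", "center"),
                                    c("A", "surface"),
                                    c("Psi", "center", "surface"))),
    list("SolidSphericalShell", list(c("F"), c("A", "center"),
                                     c("A", "surfacei"), c("A", "surfaceo"),
                                     c("A", "surface"),
                                     c("Psi", "center", "surfacei"),
                                     c("Psi", "surfacei", "surfaceo"),
                                     c("Psi", "surface", "surface"))),
    list("ThinDisk", list(c("F"), c("A", "center"), c("A", "surface"),
                          c("Psi", "center", "surface"),
                          c("Psi", "center", "rim"),
                          c("Psi", "rim", "rim"))))
  params <- c(Rg2_t = 1.2, L_t = 3, R_t = 1.4, Ri_t = 0.9, Ro_t = 1.7)
  for (cs in cases) {
    for (spec in cs[[2]]) {
      f <- subunit_factor(cs[[1]], spec[1], spec[-1], tag = "t")
      expect_equal(sk_evaluate(f, params, 0)[1], 1, tolerance = 1e-10,
                   label = paste(cs[[1]], paste(spec, collapse = ",")))
      c2 <- sk_evaluate(series_q2_coefficient(f, 1), params, 0)
      expect_lt(c2, 0)   # 1 - c q^2 with c > 0
    }
  }
})

test_that("distributed sets sharing the scatterer distribution reproduce F", {
  # A_contour == F and Psi_contour,contour' == F symbolically
  for (type in c("GaussianPolymer", "GaussianLoop", "ThinRod",
                 "ThinCircle")) {
    F <- subunit_factor(type, "F", tag = "x")
    expect_identical(deparse(subunit_factor(type, "A", "contour",
                                            tag = "x")$expr),
                     deparse(F$expr), label = type)
    expect_identical(deparse(subunit_factor(type, "Psi",
                                            c("contour", "contour"),
                                            tag = "x")$expr),
                     deparse(F$expr), label = type)
  }
  F <- subunit_factor("ThinSphericalShell", "F", tag = "x")
  expect_identical(deparse(subunit_factor("ThinSphericalShell", "A",
                                          "surface", tag = "x")$expr),
                   deparse(F$expr))
  Fd <- subunit_factor("ThinDisk", "F", tag = "x")
  expect_identical(deparse(subunit_factor("ThinDisk", "A", "surface",
                                          tag = "x")$expr),
                   deparse(Fd$expr))
})

# the two factor sweeps below make ~150 independent z comparisons; a plain
# 3 sigma cut would flag ~1 spurious excursion per run, so they use the
# Bonferroni-style allowance of 4 sigma
test_that("Gaussian polymer factors match the chain-statistics oracle", {
  set.seed(2024)
  Rg2 <- 1.3
  qv <- c(0.4, 0.9, 1.5, 2.2, 3.5)
  n <- 2e5
  checks <- list(
    c("F", "F"), c("A_end", "A", "end1"), c("A_middle", "A", "middle"),
    c("A_contour", "A", "contour"),
    c("Psi_end_end", "Psi", "end1", "end2"),
    c("Psi_end_middle", "Psi", "end1", "middle"),
    c("Psi_end_contour", "Psi", "end2", "contour"),
    c("Psi_middle_contour", "Psi", "middle", "contour"),
    c("Psi_contour_contour", "Psi", "contour", "contour"))
  for (ck in checks) {
    d <- chain_pair_dist(ck[1], Rg2, n)
    f <- subunit_factor("GaussianPolymer", ck[2], ck[-(1:2)], tag = "p")
    expect_within_z(sk_evaluate(f, c(Rg2_p = Rg2), qv), mc_sinc(d, qv),
                    z = 4)
  }
})

test_that("Gaussian loop factor matches the ring-statistics oracle", {
  set.seed(7)
  d <- loop_pair_dist(1.1, 2e5)
  f <- subunit_factor("GaussianLoop", "F", tag = "l")
  qv <- c(0.4, 1, 1.8, 3, 5)
  expect_within_z(sk_evaluate(f, c(Rg2_l = 1.1), qv), mc_sinc(d, qv))
  # small-q expansion equals 1 - q^2 Rg2 / 3 + O(q^4)
  co <- series_q2_coefficient(f, 1)
  expect_equal(sk_evaluate(co, c(Rg2_l = 2.5), 0), -2.5 / 3,
               tolerance = 1e-12)
})

test_that("rigid-body factors match pair-distance Monte Carlo", {
  qv <- c(0.5, 1.1, 2, 3.2, 4.5)
  n <- 2e5
  chk <- function(type, kind, refs, params, s1, s2, seed,
                  deterministic = FALSE) {
    f <- subunit_factor(type, kind, refs, tag = "t")
    mc <- numeric_factor_mc(s1, s2, qv, n_pairs = n, seed = seed)
    lbl <- paste(type, kind, paste(refs, collapse = ","))
    if (deterministic) {
      # fixed pair distance: the sampler has (numerically) zero spread and
      # z scores degenerate, so compare values directly
      expect_lt(max(abs(sk_evaluate(f, params, qv) - mc$value)), 1e-10,
                label = lbl)
    } else {
      dev <- abs(sk_evaluate(f, params, qv) - mc$value) / mc$stderr
      expect_lt(max(dev), 4, label = lbl)
    }
  }
  R <- 1.4; L <- 3; Ri <- 0.9; Ro <- 1.7
  pr <- c(R_t = R, L_t = L, Ri_t = Ri, Ro_t = Ro)
  ball <- point_sampler("ball", R = R)
  surf <- point_sampler("sphere_surface", R = R)
  ctr <- point_sampler("point")
  chk("SolidSphere", "F", character(), pr, ball, ball, 11)
  chk("SolidSphere", "A", "center", pr, ctr, ball, 12)
  chk("SolidSphere", "A", "surface", pr, surf, ball, 13)
  chk("SolidSphere", "Psi", c("surface", "surface"), pr, surf, surf, 14)
  shell <- point_sampler("shell_volume", Ri = Ri, Ro = Ro)
  si <- point_sampler("sphere_surface", R = Ri)
  so <- point_sampler("sphere_surface", R = Ro)
  chk("SolidSphericalShell", "F", character(), pr, shell, shell, 15)
  chk("SolidSphericalShell", "A", "center", pr, ctr, shell, 16)
  chk("SolidSphericalShell", "A", "surfacei", pr, si, shell, 17)
  chk("SolidSphericalShell", "A", "surfaceo", pr, so, shell, 18)
  chk("SolidSphericalShell", "Psi", c("surfacei", "surfaceo"), pr, si, so, 19)
  area_surf <- function(n) {
    pick <- runif(n) < Ri^2 / (Ri^2 + Ro^2)
    r <- ifelse(pick, Ri, Ro)
    r * point_sampler("sphere_surface", R = 1)(n)
  }
  chk("SolidSphericalShell", "A", "surface", pr, area_surf, shell, 20)
  disk <- point_sampler("disk_area", R = R)
  rim <- point_sampler("disk_rim", R = R)
  chk("ThinDisk", "F", character(), pr, disk, disk, 21)
  chk("ThinDisk", "A", "center", pr, ctr, disk, 22)
  chk("ThinDisk", "Psi", c("center", "rim"), pr, ctr, rim, 23,
      deterministic = TRUE)
  chk("ThinDisk", "Psi", c("rim", "rim"), pr, rim, rim, 24)
  rod <- point_sampler("rod", L = L)
  rodend <- function(n) cbind(0, 0, rep(-L / 2, n))
  chk("ThinRod", "F", character(), pr, rod, rod, 25)
  chk("ThinRod", "A", "end1", pr, rodend, rod, 26)
  circ <- point_sampler("circle", R = R)
  chk("ThinCircle", "F", character(), pr, circ, circ, 27)
  chk("ThinCircle", "A", "center", pr, ctr, circ, 28, deterministic = TRUE)
  cylv <- point_sampler("cylinder_volume", R = R, L = L)
  chk("SolidCylinder", "F", character(), pr, cylv, cylv, 29)
  chk("SolidCylinder", "A", "center", pr, ctr, cylv, 30)
})

test_that("sphere form factor value at y = pi matches the closed form", {
  # Phi(pi) = 3(sin pi - pi cos pi)/pi^3 = 3/pi^2, so F = (3/pi^2)^2
  f <- subunit_factor("SolidSphere", "F", tag = "s")
  expect_equal(sk_evaluate(f, c(R_s = 1), pi)[1], (3 / pi^2)^2,
               tolerance = 1e-12)
  mc <- numeric_factor_mc(point_sampler("ball", R = 1),
                          point_sampler("ball", R = 1),
                          pi, n_pairs = 1e6, seed = 5)
  expect_lt(abs(mc$value - (3 / pi^2)^2) / mc$stderr, 3)
})

test_that("numeric_factor_mc honors its contract", {
  s <- point_sampler("ball", R = 1)
  expect_equal(numeric_factor_mc(s, s, 0, n_pairs = 2000, seed = 1)$value, 1)
  expect_error(numeric_factor_mc(s, s, -1, n_pairs = 2000, seed = 1), "q")
  expect_error(numeric_factor_mc(s, s, 1, n_pairs = 10, seed = 1), "1000")
  a <- numeric_factor_mc(s, s, c(1, 2), n_pairs = 5000, seed = 9)
  b <- numeric_factor_mc(s, s, c(1, 2), n_pairs = 5000, seed = 9)
  expect_identical(a, b)   # deterministic given the seed
  # sphere surface pair factor at y = pi/2: sinc^2(pi/2) = (2/pi)^2
  ss <- point_sampler("sphere_surface", R = 1)
  mc <- numeric_factor_mc(ss, ss, pi / 2, n_pairs = 1e6, seed = 2)
  expect_lt(abs(mc$value - (2 / pi)^2) / mc$stderr, 3)
})

test_that("the type registry is extensible", {
  register_subunit_type("TwoPointDumbbell", "L", c(site = "specific"),
    function(kind, refs, p) {
      u <- call("*", quote(q), p$L)
      if (kind == "F") return(call("sk_sinc", u))
      if (kind == "A") return(call("sk_sinc", u))  # not used below
      1
    })
  f <- subunit_factor("TwoPointDumbbell", "F", tag = "d")
  expect_equal(sk_evaluate(f, c(L_d = 2), c(0, 1)), c(1, sin(2) / 2),
               tolerance = 1e-10)
})
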