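# Guinier-expansion sizes: radius of gyration and sigma mean-square
# distances, including the double-counting convention.

test_that("single sub-unit sizes match their defining moments", {
  w <- sk_world()
  add_unit(w, "GaussianPolymer", "P", tag = "p")
  expect_equal(size_value(radius_of_gyration2(w, "P"),
                          c(Rg2_p = 1.7, beta_p = 1)), 1.7,
               tolerance = 1e-12)
  # sphere: expansion of Phi^2 gives (3/5) R^2; MC cross-check via the
  # mean-square pair distance in a ball, halved
  w2 <- sk_world(); add_unit(w2, "SolidSphere", "S", tag = "s")
  rg <- size_value(radius_of_gyration2(w2, "S"), c(R_s = 2, beta_s = 1))
  expect_equal(rg, 0.6 * 4, tolerance = 1e-10)
  set.seed(31)
  p1 <- point_sampler("ball", R = 2)(2e5); p2 <- point_sampler("ball", R = 2)(2e5)
  msd <- rowSums((p1 - p2)^2)
  expect_lt(abs(mean(msd) / 2 - rg) / (sd(msd) / 2 / sqrt(2e5)), 3)
})

test_that("polymer SMSDs carry the documented sigma convention", {
  w <- sk_world()
  add_unit(w, "GaussianPolymer", "P", tag = "p")
  p <- c(Rg2_p = 1, beta_p = 1)
  # end to scatterers: <r^2> = 3 Rg2 (sigma = 1)
  expect_equal(size_value(smsd_ref2scat(w, "P.end1"), p), 3,
               tolerance = 1e-12)
  # contour label to scatterers: same distance set as Rg2, counted twice
  expect_equal(size_value(smsd_ref2scat(w, "P.contour#a"), p), 2,
               tolerance = 1e-12)
  expect_equal(size_value(smsd_ref2scat(w, "P.contour#a",
                                        assume_coincident_distributions =
                                          TRUE), p), 1, tolerance = 1e-12)
  # end-to-end: 6 Rg2; chain-sampler oracle
  expect_equal(size_value(smsd_ref2ref(w, "P.end1", "P.end2"), p), 6,
               tolerance = 1e-12)
  set.seed(8)
  d <- chain_pair_dist("Psi_end_end", 1, 1e5)
  expect_lt(abs(mean(d^2) - 6) / (sd(d^2) / sqrt(1e5)), 3)
  # same realized point: zero distance
  expect_equal(size_value(smsd_ref2ref(w, "P.end1", "P.end1"), p), 0)
  # sphere center to scatterers: (3/5) R^2
  w2 <- sk_world(); add_unit(w2, "SolidSphere", "S", tag = "s")
  expect_equal(size_value(smsd_ref2scat(w2, "S.center"),
                          c(R_s = 1, beta_s = 1)), 0.6, tolerance = 1e-10)
})

test_that("SMSDs add along chains (phase factors multiply)", {
  for (type in c("GaussianPolymer", "ThinRod")) {
    ch <- build_chain(n = 4, type = type, tag = "u",
                      name = paste0("ch", type))
    w <- ch$world
    p <- c(Rg2_u = 1.3, L_u = 2.5)
    total <- size_value(smsd_ref2ref(w, paste0(ch$name, ":P1.end1"),
                                     paste0(ch$name, ":P4.end2")), p)
    w1 <- sk_world()
    add_unit(w1, type, "U", tag = "u")
    single <- size_value(smsd_ref2ref(w1, "U.end1", "U.end2"), p)
    expect_equal(total, 4 * single, tolerance = 1e-10)
  }
})

test_that("consistency with numerics: finite differences of F reproduce Rg2", {
  cases <- list(
    list(build_diblock(), c(Rg2_A = 1, Rg2_B = 2, beta_A = 1, beta_B = 0.5)),
    list(build_micelle(), c(R_s = 3, Rg2_p = 1, beta_s = 1, beta_p = 1)),
    list(build_star_chain(),
         c(Rg2_pA = 1, Rg2_pB = 1.5, beta_pA = 1, beta_pB = 0.7)))
  for (cs in cases) {
    nm <- if (!is.null(cs[[1]]$name)) cs[[1]]$name else cs[[1]]$chain
    f <- form_factor(cs[[1]]$world, nm)
    rg <- size_value(radius_of_gyration2(cs[[1]]$world, nm), cs[[2]])
    h <- 1e-4
    v <- sk_evaluate(f, cs[[2]], c(h, 2 * h))
    # Richardson estimate of dF/d(q^2) at 0 (eliminates the q^4 term)
    slope <- (16 * (v[1] - 1) - (v[2] - 1)) / (12 * h^2)
    expect_equal(-3 * slope, rg, tolerance = 1e-6)
  }
})

test_that("contour-linked dendrimers of rods and polymers share Rg2", {
  # equal per-unit radius of gyration: rod L^2/12 = polymer Rg2 = 1
  dp <- build_dendrimer(generations = 3, functionality = 3,
                        type = "GaussianPolymer", linkage = "contour",
                        tag = "u", name = "Dp")
  dr <- build_dendrimer(generations = 3, functionality = 3,
                        type = "ThinRod", linkage = "contour",
                        tag = "u", name = "Dr")
  rg_p <- size_value(radius_of_gyration2(dp$world, "Dp"),
                     c(Rg2_u = 1, beta_u = 1))
  rg_r <- size_value(radius_of_gyration2(dr$world, "Dr"),
                     c(L_u = sqrt(12), beta_u = 1))
  expect_equal(rg_p, rg_r, tolerance = 1e-10)
})

test_that("size expressions stay positive at random positive bindings", {
  set.seed(12)
  sc <- build_star_chain()
  rg <- radius_of_gyration2(sc$world, "chain")
  for (i in 1:10) {
    p <- c(Rg2_pA = runif(1, 0.1, 3), Rg2_pB = runif(1, 0.1, 3),
           beta_pA = runif(1, 0.05, 2), beta_pB = runif(1, 0.05, 2))
    expect_gt(size_value(rg, p), 0)
  }
})

test_that("the hierarchical chain is five times longer than broad", {
  sc <- build_star_chain()
  p <- c(Rg2_pA = 1.2, Rg2_pB = 0.8)
  len <- size_value(smsd_ref2ref(sc$world, "chain:star1:diblock1:polyB.end2",
                                 "chain:star5:diblock3:polyB.end2"), p)
  brd <- size_value(smsd_ref2ref(sc$world, "chain:star3:diblock2:polyB.end2",
                                 "chain:star3:diblock4:polyB.end2"), p)
  # 10 A and 10 B blocks along the length, 2 + 2 across a star
  expect_equal(len, 6 * (10 * 1.2 + 10 * 0.8), tolerance = 1e-10)
  expect_equal(len / brd, 5, tolerance = 1e-12)
})
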