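# Independent numerical oracles used across the suite.  These never touch
# the package's factor table: closed forms are checked against direct
# quadrature of their defining averages or against pair-distance sampling.

# Gaussian-chain Debye function by quadrature of its defining average
# 2 * int_0^1 (1 - s) exp(-x s) ds
debye_quad <- function(x) {
  vapply(x, function(xi)
    2 * integrate(function(s) (1 - s) * exp(-xi * s), 0, 1,
                  rel.tol = 1e-12)$value, numeric(1))
}

# end-point amplitude of a Gaussian chain: int_0^1 exp(-x s) ds
end_amp_quad <- function(x) {
  vapply(x, function(xi)
    integrate(function(s) exp(-xi * s), 0, 1, rel.tol = 1e-12)$value,
    numeric(1))
}

# mean of sinc(q r) over a set of sampled distances, with standard error
mc_sinc <- function(d, q) {
  t(vapply(q, function(qi) {
    s <- ifelse(qi * d < 1e-9, 1, sin(qi * d) / (qi * d))
    c(value = mean(s), stderr = sd(s) / sqrt(length(s)))
  }, c(value = 0, stderr = 0)))
}

# distance samplers for Gaussian chain factor averages; contour positions
# s, t are uniform on [0, 1], the displacement between them is Gaussian
# with <r^2> = 6 Rg2 |s - t| (so end-to-end, |s-t| = 1, gives 6 Rg2)
gauss_dist <- function(n, msd) {
  sqrt(rowSums(matrix(rnorm(3 * n, sd = sqrt(rep(msd, 3) / 3)), ncol = 3)^2))
}

chain_pair_dist <- function(kind, Rg2, n) {
  msd <- switch(kind,
    F = 6 * Rg2 * abs(runif(n) - runif(n)),          # scatterer pairs
    A_end = 6 * Rg2 * runif(n),                      # end to scatterer
    A_middle = 6 * Rg2 * abs(runif(n) - 0.5),
    A_contour = 6 * Rg2 * abs(runif(n) - runif(n)),
    Psi_end_end = rep(6 * Rg2, n),
    Psi_end_middle = rep(3 * Rg2, n),
    Psi_end_contour = 6 * Rg2 * runif(n),
    Psi_middle_contour = 6 * Rg2 * abs(runif(n) - 0.5),
    Psi_contour_contour = 6 * Rg2 * abs(runif(n) - runif(n)),
    stop("unknown kind ", kind))
  gauss_dist(n, msd)
}

# Gaussian ring: <r^2(s,t)> = 12 Rg2 u (1 - u), u = |s - t|
loop_pair_dist <- function(Rg2, n) {
  u <- abs(runif(n) - runif(n))
  gauss_dist(n, 12 * Rg2 * u * (1 - u))
}

expect_within_z <- function(analytic, mc_table, z = 3) {
  dev <- abs(analytic - mc_table[, "value"]) /
    pmax(mc_table[, "stderr"], 1e-15)
  expect_lt(max(dev), z)
}

std_params <- c(Rg2_p = 1, beta_p = 1)
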