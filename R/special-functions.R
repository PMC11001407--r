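# Limit-safe special functions used by the sub-unit factor tables.
# Each registry entry carries:
#   fn     - vectorized numeric implementation, finite for argument >= 0
#   coef   - function(k) giving the Maclaurin coefficient of arg^k,
#            or NULL when no regular series is registered
#   py/latex/csrc/dflt - exporters (functions of the printed argument string),
#                        or NULL when the factor is evaluation-only.
# Every implementation switches to its Maclaurin series for small arguments,
# so composite expressions are finite at q = 0 without special casing.

.sk_funs <- new.env(parent = emptyenv())

reg_fun <- function(name, fn, coef, py = NULL, latex = NULL, csrc = NULL,
                    dflt = NULL) {
  assign(name, list(fn = fn, coef = coef, py = py, latex = latex,
                    csrc = csrc, dflt = dflt), envir = .sk_funs)
}

# substitute the same argument string into every %s of a template
tmpl <- function(fmt) {
  n <- lengths(regmatches(fmt, gregexpr("%s", fmt, fixed = TRUE)))
  function(a) do.call(sprintf, c(list(fmt), rep(list(a), n)))
}

# Debye function of a Gaussian chain, x = q^2 Rg^2
sk_debye <- function(x) {
  out <- numeric(length(x))
  s <- abs(x) < 1e-4
  out[s] <- 1 - x[s] / 3 + x[s]^2 / 12 - x[s]^3 / 60
  out[!s] <- 2 * (expm1(-x[!s]) + x[!s]) / x[!s]^2
  out
}

# (1 - exp(-x)) / x : polymer end amplitude
sk_exprel <- function(x) {
  out <- numeric(length(x))
  s <- abs(x) < 1e-4
  out[s] <- 1 - x[s] / 2 + x[s]^2 / 6 - x[s]^3 / 24
  out[!s] <- -expm1(-x[!s]) / x[!s]
  out
}

sk_sinc <- function(x) {
  out <- numeric(length(x))
  s <- abs(x) < 1e-4
  out[s] <- 1 - x[s]^2 / 6 + x[s]^4 / 120
  out[!s] <- sin(x[!s]) / x[!s]
  out
}

# Si(u)/u
sk_si_ratio <- function(u) {
  out <- numeric(length(u))
  s <- abs(u) < 1e-3
  out[s] <- 1 - u[s]^2 / 18 + u[s]^4 / 600
  if (any(!s)) out[!s] <- pracma::Si(u[!s]) / u[!s]
  out
}

# Dawson integral F(t): erfi identity for small t, direct quadrature of
# exp(-t^2) int_0^t exp(s^2) ds mid-range (where erfi loses digits), and
# the asymptotic series for large t.
sk_dawson <- function(t) {
  out <- numeric(length(t))
  small <- abs(t) <= 3
  mid <- !small & abs(t) <= 6
  big <- abs(t) > 6
  if (any(small))
    out[small] <- sqrt(pi) / 2 * exp(-t[small]^2) * pracma::erfi(t[small])
  if (any(mid))   # F(t) = int_0^t exp(s^2 - t^2) ds, integrand <= 1
    out[mid] <- vapply(t[mid], function(ti)
      integrate(function(s) exp(s^2 - ti^2), 0, ti,
                rel.tol = 1e-13, subdivisions = 200L)$value, numeric(1))
  if (any(big)) {
    tt <- t[big]
    acc <- 0
    term <- 1 / (2 * tt)
    for (k in 0:20) {
      acc <- acc + term
      term <- term * (2 * k + 1) / (2 * tt^2)
    }
    out[big] <- acc
  }
  out
}

# Gaussian loop factor in x = q^2 Rg^2:  (2/sqrt(a)) F(sqrt(a)/2), a = 2x.
# Maclaurin: sum_n (-1)^n x^n / (2n+1)!!
sk_loop <- function(x) {
  out <- numeric(length(x))
  s <- abs(x) < 1e-3
  out[s] <- 1 - x[s] / 3 + x[s]^2 / 15 - x[s]^3 / 105
  if (any(!s)) {
    a <- 2 * x[!s]
    out[!s] <- 2 / sqrt(a) * sk_dawson(sqrt(a) / 2)
  }
  out
}

# Thin circle factor in a = 2qR: (1/a) int_0^a J0(t) dt
sk_circle <- function(a) {
  out <- numeric(length(a))
  s <- abs(a) < 8
  if (any(s)) {
    as <- a[s]
    acc <- rep(1, length(as))
    term <- rep(1, length(as))
    for (k in 1:30) {
      term <- term * (-1) * as^2 / (4 * k^2)
      acc <- acc + term / (2 * k + 1)
    }
    out[s] <- acc
  }
  if (any(!s))
    out[!s] <- vapply(a[!s], function(ai)
      integrate(function(t) besselJ(t, 0), 0, ai,
                subdivisions = 400L, rel.tol = 1e-10)$value / ai,
      numeric(1))
  out
}

# Sphere amplitude Phi(y) = 3 (sin y - y cos y) / y^3
sk_phi <- function(y) {
  out <- numeric(length(y))
  s <- abs(y) < 1e-2
  out[s] <- 1 - y[s]^2 / 10 + y[s]^4 / 280
  out[!s] <- 3 * (sin(y[!s]) - y[!s] * cos(y[!s])) / y[!s]^3
  out
}

# Thin disk form factor in y = qR: (2/y^2) (1 - J1(2y)/y)
sk_disk <- function(y) {
  out <- numeric(length(y))
  s <- abs(y) < 1e-2
  out[s] <- 1 - y[s]^2 / 6 + y[s]^4 / 72
  out[!s] <- 2 / y[!s]^2 * (1 - besselJ(2 * y[!s], 1) / y[!s])
  out
}

# Solid cylinder, orientationally averaged.  Fixed-orientation amplitude
#   A(q, alpha) = [2 J1(qR sin a)/(qR sin a)] * sinc(qL cos a / 2),
# averaged over alpha with weight sin(alpha) on [0, pi/2].
cyl_quad <- function(q, R, L, squared) {
  gl <- .sk$cyl_gl
  if (is.null(gl)) {
    gl <- pracma::gaussLegendre(64, 0, pi / 2)
    .sk$cyl_gl <- gl
  }
  sa <- sin(gl$x)
  ca <- cos(gl$x)
  vapply(q, function(qi) {
    z <- qi * R * sa
    radial <- ifelse(abs(z) < 1e-8, 1, 2 * besselJ(ifelse(z == 0, 1, z), 1) / z)
    amp <- radial * sk_sinc(qi * L * ca / 2)
    if (squared) amp <- amp^2
    sum(gl$w * amp * sa)
  }, numeric(1))
}

sk_cyl_F <- function(q, R, L) cyl_quad(q, R, L, squared = TRUE)
sk_cyl_A <- function(q, R, L) cyl_quad(q, R, L, squared = FALSE)

dfact_odd <- function(n) prod(seq(1, n, by = 2))  # n!! for odd n

register_sk_funs <- function() {
  reg_fun("exp", exp, function(k) 1 / factorial(k),
          py = tmpl("np.exp(%s)"),
          latex = function(a) sprintf("\\exp\\!\\left(%s\\right)", a),
          csrc = tmpl("exp(%s)"),
          dflt = tmpl("exp(%s)"))
  reg_fun("sin", sin,
          function(k) if (k %% 2 == 1) (-1)^((k - 1) / 2) / factorial(k) else 0,
          py = tmpl("np.sin(%s)"),
          latex = function(a) sprintf("\\sin\\!\\left(%s\\right)", a),
          csrc = tmpl("sin(%s)"),
          dflt = tmpl("sin(%s)"))
  reg_fun("cos", cos,
          function(k) if (k %% 2 == 0) (-1)^(k / 2) / factorial(k) else 0,
          py = tmpl("np.cos(%s)"),
          latex = function(a) sprintf("\\cos\\!\\left(%s\\right)", a),
          csrc = tmpl("cos(%s)"),
          dflt = tmpl("cos(%s)"))
  reg_fun("sqrt", sqrt, NULL,   # never applied to q-dependent arguments
          py = tmpl("np.sqrt(%s)"),
          latex = function(a) sprintf("\\sqrt{%s}", a),
          csrc = tmpl("sqrt(%s)"),
          dflt = tmpl("sqrt(%s)"))
  reg_fun("sk_debye", sk_debye, function(k) 2 * (-1)^k / factorial(k + 2),
          py = tmpl("(2*(np.exp(-(%s))+(%s)-1)/(%s)**2)"),
          latex = function(a) sprintf(
            "\\frac{2\\left[\\exp(-%s)+%s-1\\right]}{\\left(%s\\right)^{2}}",
            a, a, a),
          csrc = tmpl("(2.0*(exp(-(%s))+(%s)-1.0)/((%s)*(%s)))"),
          dflt = tmpl("(2*(exp(-(%s))+(%s)-1)/(%s)^2)"))
  reg_fun("sk_exprel", sk_exprel, function(k) (-1)^k / factorial(k + 1),
          py = tmpl("((1-np.exp(-(%s)))/(%s))"),
          latex = function(a) sprintf("\\frac{1-\\exp(-%s)}{%s}", a, a),
          csrc = tmpl("((1.0-exp(-(%s)))/(%s))"),
          dflt = tmpl("((1-exp(-(%s)))/(%s))"))
  reg_fun("sk_sinc", sk_sinc,
          function(k) if (k %% 2 == 0) (-1)^(k / 2) / factorial(k + 1) else 0,
          py = tmpl("(np.sin(%s)/(%s))"),
          latex = function(a) sprintf(
            "\\frac{\\sin\\!\\left(%s\\right)}{%s}", a, a),
          csrc = tmpl("(sin(%s)/(%s))"),
          dflt = tmpl("(sin(%s)/(%s))"))
  reg_fun("sk_si_ratio", sk_si_ratio,
          function(k) if (k %% 2 == 0)
            (-1)^(k / 2) / ((k + 1) * factorial(k + 1)) else 0,
          py = tmpl("(sici(%s)[0]/(%s))"),
          latex = function(a) sprintf(
            "\\frac{\\mathrm{Si}\\!\\left(%s\\right)}{%s}", a, a),
          csrc = tmpl("(gsl_sf_Si(%s)/(%s))"),
          dflt = tmpl("(Si(%s)/(%s))"))
  reg_fun("sk_loop", sk_loop, function(k) (-1)^k / dfact_odd(2 * k + 1),
          py = tmpl("((2/np.sqrt(2*(%s)))*dawsn(np.sqrt(2*(%s))/2))"),
          latex = function(a) sprintf(
            "\\sqrt{\\frac{2}{%s}}\\,D\\!\\left(\\sqrt{\\frac{%s}{2}}\\right)",
            a, a),
          csrc = tmpl("((2.0/sqrt(2.0*(%s)))*gsl_sf_dawson(sqrt(2.0*(%s))/2.0))"),
          dflt = tmpl("((2/sqrt(2*(%s)))*dawson(sqrt(2*(%s))/2))"))
  reg_fun("sk_circle", sk_circle,
          function(k) if (k %% 2 == 0) {
            m <- k / 2
            (-1)^m / ((2 * m + 1) * 4^m * factorial(m)^2)
          } else 0,
          # closed form of int_0^a J0 via Struve functions for the export
          py = tmpl(paste0("(j0(%s)+np.pi/2*(j1(%s)*struve(0,%s)",
                           "-j0(%s)*struve(1,%s)))")),
          latex = function(a) sprintf(
            "\\frac{1}{%s}\\int_{0}^{%s} J_{0}(t)\\,\\mathrm{d}t", a, a),
          csrc = tmpl(paste0("(gsl_sf_bessel_J0(%s)+M_PI/2.0*",
                             "(gsl_sf_bessel_J1(%s)*struveH0(%s)",
                             "-gsl_sf_bessel_J0(%s)*struveH1(%s)))")),
          dflt = tmpl("(intJ0(%s)/(%s))"))
  reg_fun("sk_phi", sk_phi,
          function(k) if (k %% 2 == 0) {
            m <- k / 2
            3 * (-1)^m * 2 * (m + 1) / factorial(2 * m + 3)
          } else 0,
          py = tmpl("(3*(np.sin(%s)-(%s)*np.cos(%s))/(%s)**3)"),
          latex = function(a) sprintf(
            "\\frac{3\\left[\\sin(%s)-%s\\cos(%s)\\right]}{\\left(%s\\right)^{3}}",
            a, a, a, a),
          csrc = tmpl("(3.0*(sin(%s)-(%s)*cos(%s))/((%s)*(%s)*(%s)))"),
          dflt = tmpl("(3*(sin(%s)-(%s)*cos(%s))/(%s)^3)"))
  reg_fun("sk_disk", sk_disk,
          function(k) if (k %% 2 == 0) {
            m <- k / 2
            2 * (-1)^m / (factorial(m + 1) * factorial(m + 2))
          } else 0,
          py = tmpl("((2/(%s)**2)*(1-j1(2*(%s))/(%s)))"),
          latex = function(a) sprintf(
            "\\frac{2}{\\left(%s\\right)^{2}}\\left[1-\\frac{J_{1}(2\\,%s)}{%s}\\right]",
            a, a, a),
          csrc = NULL,
          dflt = tmpl("((2/(%s)^2)*(1-besselJ1(2*(%s))/(%s)))"))
  # multi-argument quadrature factors: evaluation-only (not exportable)
  reg_fun("sk_cyl_F", sk_cyl_F, NULL)
  reg_fun("sk_cyl_A", sk_cyl_A, NULL)
  invisible(NULL)
}
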