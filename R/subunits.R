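# Sub-unit type catalogue: reference points and the symbolic factor table
# F_I(q), A_Ialpha(q), Psi_Ialphaomega(q) for each supported sub-unit.
#
# Conventions: x = q^2 Rg2 (Gaussian types), u = qL (rod), y = qR (compact
# bodies), a = 2qR (circle).  All closed forms below are validated against
# the Monte Carlo pair-distance oracle in the test suite.  "middle" is the
# contour midpoint of a polymer or rod, so the two half chains contribute
# (1-exp(-x/2))/(x/2) and Si(u/2)/(u/2) amplitudes.
#
# Factors for distributed reference sets that share the scatterer
# distribution coincide with the form factor (contour of polymer, loop, rod
# and circle; surface of the thin shell and the disk face), and the phase
# factor between two independently realized points of such a set is again
# the form factor.

.sk_types <- new.env(parent = emptyenv())

#' Register a sub-unit type
#'
#' The built-in catalogue can be extended by registering a new type with its
#' parameters, reference points and factor table.
#'
#' @param name type name (string, case sensitive).
#' @param params character vector of structural parameter stems (e.g. "Rg2",
#'   "L", "R"); the instance tag is appended with an underscore.
#' @param refs named character vector mapping reference-point name to kind
#'   (`"specific"` or `"distributed"`).
#' @param factor_fn `function(kind, refs, p)` returning the factor as a
#'   language object; `kind` is `"F"`, `"A"` or `"Psi"`; `refs` the 0-2
#'   reference names (Psi refs sorted); `p` a named list of parameter symbol
#'   language objects.
#' @param beta_fixed optional numeric: fixed excess scattering length
#'   (the invisible Point uses 0); default NULL means a free beta parameter.
#' @export
register_subunit_type <- function(name, params, refs, factor_fn,
                                  beta_fixed = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  assign(name, list(name = name, params = params, refs = refs,
                    factor_fn = factor_fn, beta_fixed = beta_fixed),
         envir = .sk_types)
  invisible(name)
}

subunit_type <- function(name) {
  if (!exists(name, envir = .sk_types, inherits = FALSE))
    stop("unknown sub-unit type: ", name)
  get(name, envir = .sk_types, inherits = FALSE)
}

is_subunit_type <- function(name)
  is.character(name) && length(name) == 1L &&
  exists(name, envir = .sk_types, inherits = FALSE)

#' List registered sub-unit types and their reference points
#' @return named list of character vectors (reference point -> kind).
#' @export
subunit_types <- function() {
  out <- lapply(ls(.sk_types), function(n) subunit_type(n)$refs)
  names(out) <- ls(.sk_types)
  out
}

param_symbols <- function(type, tag) {
  p <- lapply(type$params, function(s) sym(paste0(s, "_", tag)))
  names(p) <- type$params
  p
}

#' Symbolic factor of a sub-unit type
#'
#' Returns the form factor (`kind = "F"`), a form factor amplitude
#' (`kind = "A"`, one reference point) or a phase factor (`kind = "Psi"`,
#' two reference points) of a single sub-unit, with parameters named after
#' `tag`.
#'
#' @param type_name registered type name, e.g. `"GaussianPolymer"`.
#' @param kind `"F"`, `"A"` or `"Psi"`.
#' @param refs character vector of 0, 1 or 2 reference point names.
#' @param tag parameter subscript (defaults to the type name).
#' @return an `sk_expr`.
#' @export
#' @examples
#' subunit_factor("GaussianPolymer", "F", tag = "p")          # Debye function
#' subunit_factor("GaussianPolymer", "A", "end1", tag = "p")
subunit_factor <- function(type_name, kind = c("F", "A", "Psi"),
                           refs = character(), tag = type_name) {
  kind <- match.arg(kind)
  type <- subunit_type(type_name)
  nref <- c(F = 0L, A = 1L, Psi = 2L)[[kind]]
  if (length(refs) != nref)
    stop(kind, " factor needs ", nref, " reference point(s), got ",
         length(refs))
  bad <- setdiff(refs, names(type$refs))
  if (length(bad))
    stop("unknown reference point '", bad[1], "' for type ", type_name,
         " (has: ", paste(names(type$refs), collapse = ", "), ")")
  p <- param_symbols(type, tag)
  e <- type$factor_fn(kind, sort(refs), p)
  if (is.null(e))
    stop(type_name, " has no ", kind, " factor for reference point(s) ",
         paste(refs, collapse = ", "))
  sk_expr(e, vapply(p, as.character, character(1)))
}

# ---- factor table helpers ---------------------------------------------------

Q <- quote(q)

f_debye  <- function(x) call("sk_debye", x)
f_exprel <- function(x) call("sk_exprel", x)
f_sinc   <- function(x) call("sk_sinc", x)
f_siru   <- function(u) call("sk_si_ratio", u)
f_phi    <- function(y) call("sk_phi", y)
half     <- function(x) mk_div(x, 2)

psi_key <- function(refs) paste(refs, collapse = "|")

register_builtin_subunits <- function() {

  register_subunit_type("GaussianPolymer", "Rg2",
    c(end1 = "specific", end2 = "specific", middle = "specific",
      contour = "distributed"),
    function(kind, refs, p) {
      x <- mk_prod(mk_pow(Q, 2), p$Rg2)
      if (kind == "F") return(f_debye(x))
      if (kind == "A") return(switch(refs,
        end1 = , end2 = f_exprel(x),
        middle = f_exprel(half(x)),
        contour = f_debye(x)))
      switch(psi_key(refs),
        "end1|end2" = call("exp", mk_neg(x)),
        "end1|middle" = , "end2|middle" = call("exp", mk_neg(half(x))),
        "contour|end1" = , "contour|end2" = f_exprel(x),
        "contour|middle" = f_exprel(half(x)),
        "contour|contour" = f_debye(x),
        NULL)
    })

  register_subunit_type("GaussianLoop", "Rg2", c(contour = "distributed"),
    function(kind, refs, p) {
      x <- mk_prod(mk_pow(Q, 2), p$Rg2)
      call("sk_loop", x)   # F = A_contour = Psi_contour,contour'
    })

  register_subunit_type("ThinRod", "L",
    c(end1 = "specific", end2 = "specific", middle = "specific",
      contour = "distributed"),
    function(kind, refs, p) {
      u <- mk_prod(Q, p$L)
      FF <- mk_diff(mk_prod(2, f_siru(u)), mk_pow(f_sinc(half(u)), 2))
      if (kind == "F") return(FF)
      if (kind == "A") return(switch(refs,
        end1 = , end2 = f_siru(u),
        middle = f_siru(half(u)),
        contour = FF))
      switch(psi_key(refs),
        "end1|end2" = f_sinc(u),
        "end1|middle" = , "end2|middle" = f_sinc(half(u)),
        "contour|end1" = , "contour|end2" = f_siru(u),
        "contour|middle" = f_siru(half(u)),
        "contour|contour" = FF,
        NULL)
    })

  register_subunit_type("ThinCircle", "R",
    c(center = "specific", contour = "distributed"),
    function(kind, refs, p) {
      a <- mk_prod(2, mk_prod(Q, p$R))
      FF <- call("sk_circle", a)
      if (kind == "F") return(FF)
      if (kind == "A") return(switch(refs,
        center = f_sinc(mk_prod(Q, p$R)),
        contour = FF))
      switch(psi_key(refs),
        "center|contour" = f_sinc(mk_prod(Q, p$R)),
        "contour|contour" = FF,
        NULL)
    })

  register_subunit_type("SolidSphere", "R",
    c(center = "specific", surface = "distributed"),
    function(kind, refs, p) {
      y <- mk_prod(Q, p$R)
      if (kind == "F") return(mk_pow(f_phi(y), 2))
      if (kind == "A") return(switch(refs,
        center = f_phi(y),
        surface = mk_prod(f_phi(y), f_sinc(y))))
      switch(psi_key(refs),
        "center|surface" = f_sinc(y),
        "surface|surface" = mk_pow(f_sinc(y), 2),
        NULL)
    })

  register_subunit_type("ThinSphericalShell", "R",
    c(center = "specific", surface = "distributed"),
    function(kind, refs, p) {
      y <- mk_prod(Q, p$R)
      if (kind == "F") return(mk_pow(f_sinc(y), 2))
      if (kind == "A") return(switch(refs,
        center = f_sinc(y),
        surface = mk_pow(f_sinc(y), 2)))
      switch(psi_key(refs),
        "center|surface" = f_sinc(y),
        "surface|surface" = mk_pow(f_sinc(y), 2),
        NULL)
    })

  register_subunit_type("SolidSphericalShell", c("Ri", "Ro"),
    c(center = "specific", surfacei = "distributed",
      surfaceo = "distributed", surface = "distributed"),
    function(kind, refs, p) {
      yi <- mk_prod(Q, p$Ri); yo <- mk_prod(Q, p$Ro)
      v3 <- mk_diff(mk_pow(p$Ro, 3), mk_pow(p$Ri, 3))
      wo <- mk_div(mk_pow(p$Ro, 3), v3)
      wi <- mk_div(mk_pow(p$Ri, 3), v3)
      Ac <- mk_diff(mk_prod(wo, f_phi(yo)), mk_prod(wi, f_phi(yi)))
      a2 <- mk_sum(mk_pow(p$Ri, 2), mk_pow(p$Ro, 2))
      fi <- mk_div(mk_pow(p$Ri, 2), a2)   # area weights of the two surfaces
      fo <- mk_div(mk_pow(p$Ro, 2), a2)
      wsinc <- mk_sum(mk_prod(fi, f_sinc(yi)), mk_prod(fo, f_sinc(yo)))
      sincs <- function(r) switch(r, surfacei = f_sinc(yi),
                                  surfaceo = f_sinc(yo), surface = wsinc)
      if (kind == "F") return(mk_pow(Ac, 2))
      if (kind == "A") return(switch(refs,
        center = Ac,
        surfacei = , surfaceo = , surface = mk_prod(Ac, sincs(refs))))
      if (refs[1] == "center") return(sincs(refs[2]))
      mk_prod(sincs(refs[1]), sincs(refs[2]))
    })

  register_subunit_type("ThinDisk", "R",
    c(center = "specific", surface = "distributed", rim = "distributed"),
    function(kind, refs, p) {
      y <- mk_prod(Q, p$R)
      FF <- call("sk_disk", y)
      Ac <- mk_pow(f_sinc(half(y)), 2)
      if (kind == "F") return(FF)
      if (kind == "A") return(switch(refs,
        center = Ac,
        surface = FF,
        rim = mcfactor_call("ThinDisk|rim_area", p["R"])))
      switch(psi_key(refs),
        "center|surface" = Ac,
        "center|rim" = f_sinc(y),
        "rim|rim" = call("sk_circle", mk_prod(2, y)),
        "rim|surface" = mcfactor_call("ThinDisk|rim_area", p["R"]),
        "surface|surface" = FF,
        NULL)
    })

  register_subunit_type("SolidCylinder", c("R", "L"),
    c(center = "specific", hull = "distributed", ends = "distributed",
      surface = "distributed"),
    function(kind, refs, p) {
      if (kind == "F") return(call("sk_cyl_F", Q, p$R, p$L))
      if (kind == "A") {
        if (refs == "center") return(call("sk_cyl_A", Q, p$R, p$L))
        return(mcfactor_call(paste0("SolidCylinder|", refs, "_volume"),
                             p[c("R", "L")]))
      }
      refs <- setdiff(refs, character())
      if (refs[1] == "center" || refs[2] == "center") {
        other <- setdiff(refs, "center")
        return(mcfactor_call(paste0("SolidCylinder|center_", other),
                             p[c("R", "L")]))
      }
      mcfactor_call(paste0("SolidCylinder|", refs[1], "_", refs[2]),
                    p[c("R", "L")])
    })

  register_subunit_type("Point", character(), c(point = "specific"),
    function(kind, refs, p) {
      if (kind == "Psi") return(1)   # same realized point
      NULL                           # no scatterers: no F or A factors
    },
    beta_fixed = 0)

  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_sk_funs()
  register_builtin_subunits()
  register_mc_samplers()
  .sk$mc_cache <- new.env(parent = emptyenv())
  invisible(NULL)
}
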