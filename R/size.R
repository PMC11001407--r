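# Guinier-expansion size measures.  Expanding the composite factors about
# q = 0 gives F = 1 - q^2 Rg^2/3 + ..., A = 1 - q^2 sigma<r^2>/6 + ...,
# Psi = 1 - q^2 sigma<r^2>/6 + ..., so the sizes are read off the q^2
# coefficient of the assembled expressions.  The double-counting factor
# sigma is 2 when the two averaged distributions coincide (e.g. a contour
# point against the chain's own scatterers); the tool cannot deduce this,
# so sigma-mean-square distances are returned undivided unless the caller
# asserts coincidence.

new_size_result <- function(expr, provenance) {
  structure(list(expr = expr, provenance = provenance), class = "sk_size")
}

#' @export
print.sk_size <- function(x, ...) {
  cat("<size expression> (length^2), from", x$provenance, "\n")
  print(x$expr)
  invisible(x)
}

#' Evaluate a size expression numerically
#' @param x an `sk_size` result.
#' @param params named numeric vector binding its parameters.
#' @return a single number (length^2).
#' @export
size_value <- function(x, params = numeric()) {
  stopifnot(inherits(x, "sk_size"))
  sk_evaluate(x$expr, params, q = 0)[1]
}

#' Squared radius of gyration of a structure
#'
#' Minus three times the q^2 coefficient of the small-q expansion of the
#' normalized composite form factor.  The result is an expression in the
#' structural parameters (and in general the contrasts).
#'
#' @param w an `sk_world`.
#' @param structure_name structure type, unit name or graph id.
#' @return an `sk_size` object.
#' @export
#' @examples
#' w <- sk_world()
#' add_unit(w, "GaussianPolymer", "A")
#' size_value(radius_of_gyration2(w, "A"), c(Rg2_A = 2, beta_A = 1))  # 2
radius_of_gyration2 <- function(w, structure_name) {
  ff <- form_factor(w, structure_name, normalized = TRUE)
  co <- series_q2_coefficient(ff, 1L)
  new_size_result(sk_simplify(-3 * co),
                  paste0("form factor of '", structure_name, "'"))
}

#' Sigma mean-square distance from a reference point to all scatterers
#'
#' Minus six times the q^2 coefficient of the normalized composite form
#' factor amplitude.  The returned value includes the double-counting
#' factor sigma: divide by two (or set `assume_coincident_distributions`)
#' when the reference distribution coincides with the scatterer
#' distribution, as for a polymer contour point.
#'
#' @param w an `sk_world`.
#' @param ref reference-point address.
#' @param assume_coincident_distributions divide the result by two.
#' @return an `sk_size` object.
#' @export
smsd_ref2scat <- function(w, ref, assume_coincident_distributions = FALSE) {
  amp <- form_factor_amplitude(w, ref, normalized = TRUE)
  co <- series_q2_coefficient(amp, 1L)
  e <- sk_simplify(-6 * co)
  if (assume_coincident_distributions) e <- sk_simplify(e / 2)
  new_size_result(e, paste0("form factor amplitude at '", ref, "'"))
}

#' Sigma mean-square distance between two reference points
#'
#' Minus six times the q^2 coefficient of the composite phase factor; zero
#' when both addresses denote the same realized point.  As with
#' [smsd_ref2scat()], the double-counting factor is left in.
#'
#' @param w an `sk_world`.
#' @param ref1,ref2 reference-point addresses in the same structure.
#' @param assume_coincident_distributions divide the result by two.
#' @return an `sk_size` object.
#' @export
smsd_ref2ref <- function(w, ref1, ref2,
                         assume_coincident_distributions = FALSE) {
  psi <- phase_factor(w, ref1, ref2)
  co <- series_q2_coefficient(psi, 1L)
  e <- sk_simplify(-6 * co)
  if (assume_coincident_distributions) e <- sk_simplify(e / 2)
  new_size_result(e, paste0("phase factor '", ref1, "' <-> '", ref2, "'"))
}

#' @rdname radius_of_gyration2
#' @export
RadiusOfGyration2 <- radius_of_gyration2

#' @rdname smsd_ref2scat
#' @export
SMSD_ref2scat <- smsd_ref2scat

#' @rdname smsd_ref2ref
#' @export
SMSD_ref2ref <- smsd_ref2ref
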