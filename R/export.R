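# Expression export.  Four dialects: latex, csrc, python, dflt.
# python uses ** for powers; csrc uses pow() for fractional powers and
# expands small integer powers into products; dflt is plain ^-power text.

.sk_dialects <- c("latex", "csrc", "python", "dflt")

latex_sym <- function(nm) {
  if (nm == "q") return("q")
  parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
  base <- switch(parts[1],
                 beta = "\\beta", Rg2 = "R_{g}^{2}", R = "R", L = "L",
                 Ri = "R_{i}", Ro = "R_{o}", parts[1])
  if (length(parts) > 1)
    sprintf("{%s}_{\\mathrm{%s}}", base, paste(parts[-1], collapse = ","))
  else base
}

needs_paren <- function(txt) grepl("[-+*/ ]", txt) && !grepl("^\\\\", txt)

paren <- function(txt, dialect) {
  if (dialect == "latex") sprintf("\\left(%s\\right)", txt)
  else sprintf("(%s)", txt)
}

export_lang <- function(e, dialect) {
  if (is.numeric(e)) {
    if (e == round(e) && abs(e) < 1e15) return(format(e, scientific = FALSE))
    return(format(e, digits = 17))
  }
  if (is.name(e)) {
    nm <- as.character(e)
    return(if (dialect == "latex") latex_sym(nm) else nm)
  }
  if (is.character(e)) return(e)
  if (!is.call(e)) stop("cannot export node of class ", class(e))
  fname <- as.character(e[[1]])
  args <- as.list(e)[-1]
  if (fname %in% c("MCFACTOR", "MCQ2"))
    stop("expression contains a numeric-tier Monte Carlo factor (",
         as.character(args[[1]]),
         "); it has no closed form - evaluate it numerically with ",
         "sk_evaluate()/evaluate_curve() instead of exporting")
  if (fname %in% c("sk_cyl_F", "sk_cyl_A"))
    stop("cylinder quadrature factors have no closed-form export; ",
         "evaluate them numerically instead")
  ex <- function(a) export_lang(a, dialect)
  ops <- c("+", "-", "*", "/", "^")
  if (fname %in% c("SUM", "PROD")) {
    sep <- if (fname == "SUM") " + " else " * "
    parts <- vapply(args, function(a) {
      t <- ex(a)
      if (fname == "PROD" && grepl("[-+]", t)) paren(t, dialect) else t
    }, character(1))
    return(paste(parts, collapse = sep))
  }
  if (fname %in% ops) {
    if (length(args) == 1L) return(sprintf("-%s", maybe_paren(ex(args[[1]]), dialect)))
    a <- ex(args[[1]]); b <- ex(args[[2]])
    return(switch(fname,
      "+" = sprintf("%s + %s", a, b),
      "-" = sprintf("%s - %s", a, maybe_paren(b, dialect)),
      "*" = {
        if (dialect == "latex")
          sprintf("%s \\, %s", maybe_paren(a, dialect), maybe_paren(b, dialect))
        else sprintf("%s*%s", maybe_paren(a, dialect), maybe_paren(b, dialect))
      },
      "/" = {
        if (dialect == "latex") sprintf("\\frac{%s}{%s}", a, b)
        else sprintf("%s/%s", maybe_paren(a, dialect), maybe_paren(b, dialect))
      },
      "^" = export_pow(args[[1]], args[[2]], dialect)))
  }
  if (fname == "(") return(paren(ex(args[[1]]), dialect))
  entry <- if (exists(fname, envir = .sk_funs, inherits = FALSE))
    get(fname, envir = .sk_funs) else stop("unknown function: ", fname)
  printer <- entry[[if (dialect == "python") "py" else dialect]]
  if (is.null(printer))
    stop("function ", fname, " has no ", dialect, " export")
  printer(ex(args[[1]]))
}

maybe_paren <- function(txt, dialect) {
  if (grepl("[-+*/ ]", txt)) paren(txt, dialect) else txt
}

export_pow <- function(base, expo, dialect) {
  b <- export_lang(base, dialect)
  e <- export_lang(expo, dialect)
  bp <- maybe_paren(b, dialect)
  switch(dialect,
    latex = sprintf("{%s}^{%s}", bp, e),
    python = sprintf("%s**%s", bp, maybe_paren(e, dialect)),
    dflt = sprintf("%s^%s", bp, maybe_paren(e, dialect)),
    csrc = {
      if (num1(expo) && expo == round(expo) && expo >= 2 && expo <= 4)
        paste(rep(bp, expo), collapse = "*")   # expand small integer powers
      else sprintf("pow(%s, %s)", b, e)
    })
}

#' Export a scattering expression as text
#'
#' @param expr an `sk_expr`.
#' @param dialect one of `"latex"`, `"csrc"`, `"python"`, `"dflt"`.
#'   The python dialect uses `**` for powers (preamble via
#'   [sk_python_preamble()]); csrc uses `pow()` for fractional powers and
#'   expands small integer powers; dflt is plain `^`-power text.
#' @return a character string.
#' @export
#' @examples
#' sk_export(sk_expr(quote(x^2), "x"), "python")   # "x**2"
sk_export <- function(expr, dialect = c("dflt", "latex", "csrc", "python")) {
  expr <- as_sk_expr(expr)
  dialect <- match.arg(dialect, .sk_dialects)
  export_lang(expr$expr, dialect)
}

#' Python preamble for exported expressions
#'
#' Returns import lines under which every python-dialect export evaluates
#' (numpy plus the scipy special functions used by rod, circle and loop
#' factors).
#'
#' @return a character string of python code.
#' @export
sk_python_preamble <- function() {
  paste("import numpy as np",
        "from scipy.special import sici, j0, j1, struve, dawsn",
        sep = "\n")
}
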