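# ScatteringExpr: a symbolic expression over q and named structural/contrast
# parameters, represented as a base-R language object plus a symbol registry.

#' Create a scattering expression
#'
#' Wraps an R language object (or a number) as a symbolic scattering
#' expression.  Every free symbol must be either `q` (momentum transfer,
#' inverse length) or listed in `params`.
#'
#' @param expr a language object (e.g. from `quote()`), or a single number.
#' @param params character vector of parameter symbol names used in `expr`.
#' @return an object of class `sk_expr`.
#' @export
#' @examples
#' e <- sk_expr(quote(exp(-q^2 * Rg2)), "Rg2")
#' sk_evaluate(e, c(Rg2 = 1), q = c(0, 1))
sk_expr <- function(expr, params = character()) {
  if (is.numeric(expr) && length(expr) == 1L) expr <- as.vector(expr)
  stopifnot(is.numeric(expr) || is.language(expr))
  free <- setdiff(all.vars(expr), "q")
  unknown <- setdiff(free, params)
  if (length(unknown))
    stop("unregistered symbols in expression: ", paste(unknown, collapse = ", "))
  structure(list(expr = expr, params = sort(unique(params))),
            class = "sk_expr")
}

is_sk_expr <- function(x) inherits(x, "sk_expr")

as_sk_expr <- function(x) {
  if (is_sk_expr(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(sk_expr(x))
  stop("cannot coerce to sk_expr")
}

#' @export
print.sk_expr <- function(x, ...) {
  cat("<scattering expression>\n")
  txt <- paste(deparse(x$expr, width.cutoff = 120L), collapse = "\n  ")
  if (nchar(txt) > 2000) txt <- paste0(substr(txt, 1, 2000), " ...")
  cat(" ", txt, "\n")
  if (length(x$params))
    cat("  parameters:", paste(x$params, collapse = ", "), "\n")
  invisible(x)
}

# ---- constant-folding call constructors -------------------------------------

num1 <- function(e) is.numeric(e) && length(e) == 1L

mk_sum <- function(a, b) {
  if (num1(a) && num1(b)) return(a + b)
  if (num1(a) && a == 0) return(b)
  if (num1(b) && b == 0) return(a)
  call("+", a, b)
}

mk_diff <- function(a, b) {
  if (num1(a) && num1(b)) return(a - b)
  if (num1(b) && b == 0) return(a)
  if (num1(a) && a == 0) return(mk_neg(b))
  call("-", a, b)
}

mk_neg <- function(a) {
  if (num1(a)) return(-a)
  call("-", a)
}

mk_prod <- function(a, b) {
  if (num1(a) && num1(b)) return(a * b)
  if (num1(a)) { if (a == 0) return(0); if (a == 1) return(b) }
  if (num1(b)) { if (b == 0) return(0); if (b == 1) return(a) }
  call("*", a, b)
}

mk_div <- function(a, b) {
  if (num1(b) && b == 0) stop("division by zero in expression")
  if (num1(a) && a == 0) return(0)
  if (num1(b) && b == 1) return(a)
  if (num1(a) && num1(b)) return(a / b)
  call("/", a, b)
}

mk_pow <- function(a, b) {
  if (num1(b)) {
    if (b == 0) return(1)
    if (b == 1) return(a)
  }
  if (num1(a) && num1(b)) return(a ^ b)
  call("^", a, b)
}

# n-ary sum/product nodes keep big composite expressions flat (no deep
# nesting), which matters for structures with thousands of terms.
SUM  <- function(...) Reduce(`+`, list(...), accumulate = FALSE)
PROD <- function(...) Reduce(`*`, list(...), accumulate = FALSE)

mk_nary <- function(fname, terms) {
  terms <- terms[!vapply(terms, function(t) num1(t) &&
                           t == (if (fname == "SUM") 0 else 1), logical(1))]
  if (fname == "PROD" && any(vapply(terms, function(t) num1(t) && t == 0,
                                    logical(1)))) return(0)
  if (length(terms) == 0L) return(if (fname == "SUM") 0 else 1)
  nums <- vapply(terms, num1, logical(1))
  if (all(nums)) {
    v <- unlist(terms)
    return(if (fname == "SUM") sum(v) else prod(v))
  }
  if (length(terms) == 1L) return(terms[[1]])
  as.call(c(as.name(fname), terms))
}

# arithmetic on sk_expr objects
#' @export
Ops.sk_expr <- function(e1, e2) {
  if (missing(e2)) {
    e1 <- as_sk_expr(e1)
    if (.Generic == "-") return(sk_expr(mk_neg(e1$expr), e1$params))
    if (.Generic == "+") return(e1)
    stop("unsupported unary operator for sk_expr: ", .Generic)
  }
  a <- as_sk_expr(e1); b <- as_sk_expr(e2)
  f <- switch(.Generic, "+" = mk_sum, "-" = mk_diff, "*" = mk_prod,
              "/" = mk_div, "^" = mk_pow,
              stop("unsupported operator for sk_expr: ", .Generic))
  sk_expr(f(a$expr, b$expr), union(a$params, b$params))
}

sym <- function(name) as.name(name)

# ---- substitution -----------------------------------------------------------

sub_lang <- function(e, bind) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(bind)) return(bind[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- sub_lang(e[[i]], bind)
    return(e)
  }
  e
}

#' Substitute parameters in a scattering expression
#'
#' Replaces registered parameter symbols by numbers or other expressions;
#' the symbol registry of the result is updated accordingly.
#'
#' @param expr an `sk_expr`.
#' @param bindings named list; values are numbers or `sk_expr` objects.
#' @return an `sk_expr` with the substitutions applied.
#' @export
sk_substitute <- function(expr, bindings) {
  expr <- as_sk_expr(expr)
  stopifnot(is.list(bindings), !is.null(names(bindings)))
  unknown <- setdiff(names(bindings), expr$params)
  if (length(unknown))
    stop("unknown symbol(s) in bindings: ", paste(unknown, collapse = ", "))
  newpars <- character()
  bind <- lapply(bindings, function(v) {
    if (is_sk_expr(v)) { newpars <<- union(newpars, v$params); v$expr }
    else if (is.numeric(v) && length(v) == 1L) as.vector(v)
    else if (is.language(v)) stop("bind raw language via sk_expr() so its symbols are registered")
    else stop("binding values must be numbers or sk_expr objects")
  })
  out <- sub_lang(expr$expr, bind)
  sk_expr(out, union(setdiff(expr$params, names(bindings)), newpars))
}

# ---- simplification (explicit pass only; nothing is simplified on the fly) --

fold_lang <- function(e) {
  if (!is.call(e)) return(e)
  fname <- as.character(e[[1]])
  args <- lapply(as.list(e)[-1], fold_lang)
  if (fname %in% c("SUM", "PROD")) return(mk_nary(fname, args))
  if (length(args) == 2L) {
    f <- switch(fname, "+" = mk_sum, "-" = mk_diff, "*" = mk_prod,
                "/" = mk_div, "^" = mk_pow, NULL)
    if (!is.null(f)) return(f(args[[1]], args[[2]]))
  }
  if (length(args) == 1L && fname == "-") return(mk_neg(args[[1]]))
  if (length(args) == 1L && fname == "(") return(args[[1]])
  as.call(c(e[[1]], args))
}

#' Simplify a scattering expression
#'
#' scatterkit never simplifies expressions automatically; this explicit pass
#' folds numeric sub-expressions and removes arithmetic identities
#' (`x*1`, `x+0`, `x^1`, ...).
#'
#' @param expr an `sk_expr`.
#' @return a simplified `sk_expr`.
#' @export
sk_simplify <- function(expr) {
  expr <- as_sk_expr(expr)
  out <- fold_lang(expr$expr)
  sk_expr(out, intersect(expr$params, all.vars(out)))
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a scattering expression numerically
#'
#' All parameters must be bound; `q` may be a vector and may include 0
#' (every built-in factor is limit-safe there).
#'
#' @param expr an `sk_expr`.
#' @param params named numeric vector binding every parameter.
#' @param q numeric vector of momentum-transfer values, `q >= 0`.
#' @return numeric vector of the same length as `q`.
#' @export
sk_evaluate <- function(expr, params = numeric(), q) {
  expr <- as_sk_expr(expr)
  stopifnot(is.numeric(q))
  if (any(q < 0)) stop("q must be non-negative")
  missing <- setdiff(expr$params, names(params))
  if (length(missing))
    stop("unbound parameter(s): ", paste(missing, collapse = ", "))
  env <- new.env(parent = emptyenv())
  for (nm in names(params)) assign(nm, as.numeric(params[[nm]]), envir = env)
  assign("q", as.numeric(q), envir = env)
  cache <- new.env(parent = emptyenv())
  v <- eval_lang(expr$expr, env, cache)
  if (length(v) == 1L) v <- rep(v, length(q))
  if (any(!is.finite(v))) stop("expression evaluated to non-finite values")
  v
}

eval_lang <- function(e, env, cache) {
  if (is.numeric(e)) return(e)
  if (is.name(e)) {
    nm <- as.character(e)
    if (!exists(nm, envir = env, inherits = FALSE))
      stop("unbound symbol: ", nm)
    return(get(nm, envir = env, inherits = FALSE))
  }
  if (!is.call(e)) stop("cannot evaluate expression node of class ", class(e))
  fname <- as.character(e[[1]])
  if (fname == "SUM" || fname == "PROD") {
    acc <- if (fname == "SUM") 0 else 1
    for (i in seq_along(e)[-1]) {
      v <- eval_lang(e[[i]], env, cache)
      acc <- if (fname == "SUM") acc + v else acc * v
    }
    return(acc)
  }
  # memoize repeated small factors (shared across thousands of terms)
  key <- NULL
  if (fname %in% c("exp", "sin", "cos", "sqrt", "^") ||
      exists(fname, envir = .sk_funs, inherits = FALSE)) {
    key <- paste(deparse(e, width.cutoff = 500L), collapse = "")
    if (nchar(key) <= 400L &&
        exists(key, envir = cache, inherits = FALSE))
      return(get(key, envir = cache, inherits = FALSE))
    if (nchar(key) > 400L) key <- NULL
  }
  args <- lapply(as.list(e)[-1], function(a) {
    if (is.character(a)) a else eval_lang(a, env, cache)
  })
  v <- switch(fname,
    "+" = if (length(args) == 1L) args[[1]] else args[[1]] + args[[2]],
    "-" = if (length(args) == 1L) -args[[1]] else args[[1]] - args[[2]],
    "*" = args[[1]] * args[[2]],
    "/" = args[[1]] / args[[2]],
    "^" = args[[1]] ^ args[[2]],
    "(" = args[[1]],
    "exp" = exp(args[[1]]),
    "sin" = sin(args[[1]]),
    "cos" = cos(args[[1]]),
    "sqrt" = sqrt(args[[1]]),
    {
      if (!exists(fname, envir = .sk_funs, inherits = FALSE))
        stop("unknown function in expression: ", fname)
      do.call(get(fname, envir = .sk_funs)$fn, args)
    })
  if (!is.null(key)) assign(key, v, envir = cache)
  v
}

free_params <- function(e) setdiff(all.vars(e), "q")
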