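# Small-q series machinery.  A series is a plain list of language objects,
# coefficients of q^0 .. q^ord; coefficients are built with constant folding,
# so that structural zeros stay the numeric 0 (this is what lets the engine
# recognize removable singularities such as the Debye function's x^2
# denominator).

ser_zero <- function(ord) as.list(rep(0, ord + 1))

is_zero_coef <- function(c) num1(c) && c == 0

ser_add <- function(a, b) Map(mk_sum, a, b)
ser_sub <- function(a, b) Map(mk_diff, a, b)
ser_neg <- function(a) lapply(a, mk_neg)
ser_scale <- function(a, s) lapply(a, function(c) mk_prod(s, c))

ser_mul <- function(a, b) {
  ord <- length(a) - 1L
  out <- ser_zero(ord)
  for (i in 0:ord) {
    if (is_zero_coef(a[[i + 1]])) next
    for (j in 0:(ord - i)) {
      if (is_zero_coef(b[[j + 1]])) next
      out[[i + j + 1]] <- mk_sum(out[[i + j + 1]],
                                 mk_prod(a[[i + 1]], b[[j + 1]]))
    }
  }
  out
}

# division with removable-singularity shift: both numerator and denominator
# may share leading structural zeros.  Coefficients of the quotient beyond
# (working order - shift) would need numerator terms we did not compute; they
# are marked with a sentinel and the expansion is retried at higher order if
# one of them is actually requested.
need_order <- function(msg) {
  stop(structure(class = c("sk_need_order", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# identically-zero test for a coefficient expression: structural zero, or
# numerically zero at two fixed irrational parameter assignments (catches
# symbolic cancellations like -Rg2 + Rg2 that folding cannot see)
coef_is_zero <- function(e) {
  if (num1(e)) return(e == 0)
  vars <- all.vars(e)
  if (".INVALID" %in% vars) return(FALSE)
  for (base in c(0.6180339887498949, 1.3247179572447460)) {
    env <- new.env(parent = emptyenv())
    for (i in seq_along(vars))
      assign(vars[i], base^i * 0.9241388, envir = env)
    v <- tryCatch(eval_lang(e, env, new.env(parent = emptyenv())),
                  error = function(err) NA_real_)
    if (!isTRUE(abs(v) < 1e-9)) return(FALSE)
  }
  TRUE
}

ser_div <- function(a, b) {
  ord <- length(a) - 1L
  shift <- 0L
  while (shift <= ord && coef_is_zero(b[[shift + 1]])) {
    if (!coef_is_zero(a[[shift + 1]]))
      stop("expression is not analytic at q = 0 (pole in small-q expansion)")
    a[[shift + 1]] <- 0
    b[[shift + 1]] <- 0
    shift <- shift + 1L
  }
  if (shift > ord)
    need_order("denominator vanishes to the working order")
  if (shift > 0L) {
    pad <- rep(list(quote(.INVALID)), shift)
    an <- c(a[(shift + 1):(ord + 1)], pad)
    bn <- c(b[(shift + 1):(ord + 1)], ser_zero(shift - 1L))
  } else { an <- a; bn <- b }
  b0 <- bn[[1]]
  out <- ser_zero(ord)
  for (k in 0:ord) {
    acc <- an[[k + 1]]
    if (k > 0) for (i in 0:(k - 1)) {
      if (is_zero_coef(out[[i + 1]]) || is_zero_coef(bn[[k - i + 1]])) next
      acc <- mk_diff(acc, mk_prod(out[[i + 1]], bn[[k - i + 1]]))
    }
    out[[k + 1]] <- mk_div(acc, b0)
  }
  out
}

ser_ipow <- function(a, n) {
  ord <- length(a) - 1L
  out <- ser_zero(ord); out[[1]] <- 1
  for (i in seq_len(n)) out <- ser_mul(out, a)
  out
}

# compose a registered Maclaurin series f(u) = sum coef_k u^k with an
# argument series whose constant term must vanish (all our factor arguments
# are proportional to q or q^2).
ser_compose <- function(coef_fun, a, fname) {
  ord <- length(a) - 1L
  if (!is_zero_coef(a[[1]]))
    stop("cannot series-expand ", fname,
         " of an argument with nonzero value at q = 0")
  out <- ser_zero(ord)
  out[[1]] <- coef_fun(0)
  pw <- NULL
  for (k in seq_len(ord)) {
    pw <- if (is.null(pw)) a else ser_mul(pw, a)
    ck <- coef_fun(k)
    if (ck != 0) out <- ser_add(out, ser_scale(pw, ck))
  }
  out
}

lang_series <- function(e, ord, cache) {
  if (is.numeric(e)) { out <- ser_zero(ord); out[[1]] <- e; return(out) }
  if (is.name(e)) {
    out <- ser_zero(ord)
    if (identical(as.character(e), "q")) {
      if (ord >= 1) out[[2]] <- 1
    } else out[[1]] <- e
    return(out)
  }
  if (!is.call(e)) stop("cannot expand node of class ", class(e))
  fname <- as.character(e[[1]])
  key <- NULL
  if (!(fname %in% c("SUM", "PROD")) && length(e) <= 3L) {
    key <- paste(deparse(e, width.cutoff = 500L), collapse = "")
    if (nchar(key) > 400L) key <- NULL
    else {
      cached <- cache[[key]]
      if (!is.null(cached)) return(cached)
    }
  }
  args <- as.list(e)[-1]
  out <- switch(fname,
    "SUM" = {
      # keep coefficient sums flat: thousands of terms would otherwise
      # nest into a recursion-breaking left comb
      pieces <- lapply(seq_len(ord + 1L), function(k) vector("list", 0L))
      for (a in args) {
        s <- lang_series(a, ord, cache)
        for (k in seq_len(ord + 1L))
          if (!is_zero_coef(s[[k]]))
            pieces[[k]][[length(pieces[[k]]) + 1L]] <- s[[k]]
      }
      lapply(pieces, function(p) mk_nary("SUM", p))
    },
    "PROD" = {
      sl <- lapply(args, function(a) lang_series(a, ord, cache))
      done <- FALSE
      res <- NULL
      if (ord <= 3L) {
        # fast path: every factor is either q-free or a normalized
        # 1 + c q^2 (+ c3 q^3) shape, which covers all composite terms
        consts <- list(); quad <- list(); cub <- list(); ok <- TRUE
        for (s in sl) {
          if (all(vapply(s[-1], is_zero_coef, logical(1)))) {
            consts[[length(consts) + 1L]] <- s[[1]]
          } else if (num1(s[[1]]) && s[[1]] == 1 &&
                     (ord < 1L || is_zero_coef(s[[2]]))) {
            if (ord >= 2L && !is_zero_coef(s[[3]]))
              quad[[length(quad) + 1L]] <- s[[3]]
            if (ord >= 3L && !is_zero_coef(s[[4]]))
              cub[[length(cub) + 1L]] <- s[[4]]
          } else { ok <- FALSE; break }
        }
        if (ok) {
          cst <- mk_nary("PROD", consts)
          res <- ser_zero(ord)
          res[[1]] <- cst
          if (ord >= 2L) res[[3]] <- mk_prod(cst, mk_nary("SUM", quad))
          if (ord >= 3L) res[[4]] <- mk_prod(cst, mk_nary("SUM", cub))
          done <- TRUE
        }
      }
      if (!done) {
        res <- ser_zero(ord); res[[1]] <- 1
        for (s in sl) res <- ser_mul(res, s)
      }
      res
    },
    "+" = if (length(args) == 1L) lang_series(args[[1]], ord, cache) else
      ser_add(lang_series(args[[1]], ord, cache),
              lang_series(args[[2]], ord, cache)),
    "-" = if (length(args) == 1L) ser_neg(lang_series(args[[1]], ord, cache)) else
      ser_sub(lang_series(args[[1]], ord, cache),
              lang_series(args[[2]], ord, cache)),
    "*" = ser_mul(lang_series(args[[1]], ord, cache),
                  lang_series(args[[2]], ord, cache)),
    "/" = ser_div(lang_series(args[[1]], ord, cache),
                  lang_series(args[[2]], ord, cache)),
    "(" = lang_series(args[[1]], ord, cache),
    "^" = {
      base <- lang_series(args[[1]], ord, cache)
      ex <- args[[2]]
      if (num1(ex) && ex == round(ex) && ex >= 0) ser_ipow(base, ex)
      else if (num1(ex) && ex == round(ex))
        ser_div({ o <- ser_zero(ord); o[[1]] <- 1; o }, ser_ipow(base, -ex))
      else if (all(vapply(base[-1], is_zero_coef, logical(1)))) {
        o <- ser_zero(ord); o[[1]] <- mk_pow(base[[1]], ex); o
      } else stop("cannot series-expand non-integer power of a q-dependent base")
    },
    "MCFACTOR" = mcfactor_series(e, ord),
    "sk_cyl_F" = cyl_series(args, ord, amp = FALSE),
    "sk_cyl_A" = cyl_series(args, ord, amp = TRUE),
    {
      entry <- if (exists(fname, envir = .sk_funs, inherits = FALSE))
        get(fname, envir = .sk_funs) else
        stop("unknown function in expression: ", fname)
      if (is.null(entry$coef))
        stop("no small-q series registered for ", fname)
      ser_compose(entry$coef, lang_series(args[[1]], ord, cache), fname)
    })
  if (!is.null(key)) cache[[key]] <- out
  out
}

# Cylinder factors: second moment <r^2> about the center is R^2/2 + L^2/12;
# the orientationally averaged amplitude expands as 1 - q^2 <r^2>/6 and the
# form factor as 1 - q^2 <r^2>/3.  Higher orders are not registered.
cyl_series <- function(args, ord, amp) {
  if (ord > 3)
    stop("cylinder quadrature factors are expanded to order q^2 only")
  R <- args[[2]]; L <- args[[3]]
  r2 <- mk_sum(mk_div(mk_pow(R, 2), 2), mk_div(mk_pow(L, 2), 12))
  out <- ser_zero(ord); out[[1]] <- 1
  if (ord >= 2)
    out[[3]] <- mk_prod(-1 / (if (amp) 6 else 3), r2)
  out
}

#' Coefficient of the small-q expansion in powers of q^2
#'
#' Expands an expression about q = 0 and returns the coefficient of
#' `(q^2)^order` as an expression in the remaining parameters.  Order 0 of
#' any normalized factor is 1; order 1 carries the Guinier size information.
#'
#' @param expr an `sk_expr` with a regular expansion in powers of q^2.
#' @param order non-negative integer.
#' @return an `sk_expr` for the requested coefficient.
#' @export
#' @examples
#' d <- sk_expr(quote(sk_debye(q^2 * Rg2)), "Rg2")
#' series_q2_coefficient(d, 1)   # -Rg2/3
series_q2_coefficient <- function(expr, order) {
  expr <- as_sk_expr(expr)
  stopifnot(length(order) == 1L, order >= 0, order == round(order))
  co <- NULL
  for (extra in c(0L, 4L, 8L, 16L)) {
    res <- tryCatch({
      cache <- new.env(parent = emptyenv())
      s <- lang_series(expr$expr, 2L * order + extra, cache)
      s[[2L * order + 1L]]
    }, sk_need_order = function(e) NULL)
    if (!is.null(res) && !(".INVALID" %in% all.vars(res))) { co <- res; break }
  }
  if (is.null(co))
    stop("small-q expansion failed: expression needs more than 16 extra ",
         "orders to resolve its removable singularities")
  co <- fold_lang(co)
  sk_expr(co, intersect(expr$params, all.vars(co)))
}
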