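# q grids, curve evaluation and two-column curve files.

#' Construct a q grid
#'
#' @param qmin,qmax grid bounds (inverse length); `qmin > 0` for log
#'   spacing and `qmin < qmax` unless `n = 1`.
#' @param n number of points.
#' @param spacing `"log"` (log-equidistant, the usual choice for scattering
#'   curves) or `"linear"`.
#' @return numeric vector of class `sk_qgrid`, endpoints included.
#' @export
#' @examples
#' g <- make_q_grid(0.01, 50, 400)   # the standard 400-point log grid
make_q_grid <- function(qmin, qmax, n, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(length(qmin) == 1L, length(qmax) == 1L, n >= 1)
  if (n == 1L) {
    if (qmin != qmax) stop("n = 1 requires qmin == qmax")
    return(structure(qmin, class = "sk_qgrid"))
  }
  if (!(qmin < qmax)) stop("qmin must be smaller than qmax")
  if (spacing == "log" && qmin <= 0)
    stop("log spacing requires qmin > 0")
  g <- switch(spacing,
              log = exp(seq(log(qmin), log(qmax), length.out = n)),
              linear = seq(qmin, qmax, length.out = n))
  structure(g, class = "sk_qgrid")
}

new_curve <- function(q, I, stderr = NULL) {
  stopifnot(length(q) == length(I),
            is.null(stderr) || length(stderr) == length(q))
  df <- data.frame(q = as.numeric(q), I = as.numeric(I))
  if (!is.null(stderr)) df$stderr <- as.numeric(stderr)
  class(df) <- c("sk_curve", "data.frame")
  df
}

#' Evaluate a scattering expression on a q grid
#'
#' @param expr an `sk_expr` (e.g. from [form_factor()]).
#' @param params named numeric vector binding every parameter of `expr`.
#' @param grid numeric q vector, e.g. from [make_q_grid()].
#' @return an `sk_curve` data frame with columns `q` and `I`.
#' @export
evaluate_curve <- function(expr, params, grid) {
  v <- sk_evaluate(expr, params, q = as.numeric(grid))
  cv <- new_curve(as.numeric(grid), v)
  attr(cv, "params") <- params
  cv
}

#' Write a scattering curve to a text file
#'
#' Whitespace-separated two-column (three with Monte Carlo standard errors)
#' plain text; `#`-prefixed header lines record the parameter bindings so
#' the curve can be regenerated.  The conventional extension is `.q`.
#'
#' @param curve an `sk_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sk_curve"))
  params <- attr(curve, "params")
  hdr <- c(sprintf("# scatterkit curve, %d points", nrow(curve)),
           if (length(params))
             sprintf("# param %s = %.17g", names(params), as.numeric(params)),
           paste0("# columns: q I", if ("stderr" %in% names(curve))
             " stderr" else ""))
  cols <- c("q", "I", if ("stderr" %in% names(curve)) "stderr")
  body <- do.call(sprintf,
                  c(list(paste(rep("%.12e", length(cols)), collapse = " ")),
                    unname(as.list(curve[cols]))))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a scattering curve written by [write_curve()]
#'
#' @param path file path.
#' @return an `sk_curve`; recorded parameter bindings are restored into the
#'   `params` attribute.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  m <- regmatches(hdr, regexec("^# param ([^ ]+) = (.+)$", hdr))
  pm <- Filter(length, m)
  params <- setNames(vapply(pm, function(x) as.numeric(x[3]), numeric(1)),
                     vapply(pm, function(x) x[2], character(1)))
  dat <- do.call(rbind, lapply(strsplit(trimws(body), "[ \t]+"), as.numeric))
  cv <- new_curve(dat[, 1], dat[, 2],
                  stderr = if (ncol(dat) >= 3) dat[, 3] else NULL)
  attr(cv, "params") <- params
  cv
}
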