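# Pair-distance Monte Carlo: the numeric tier of the factor table.
# Every rigid-body factor is the average of sinc(q r) over the appropriate
# pair-distance distribution, because the orientational average of a fixed
# displacement r is sinc(q r).  Factors without a practical closed form
# (disk rim, cylinder hull/ends/surface) are evaluated this way, memoized,
# with a fixed seed so expressions stay deterministic.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

runit_vec <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Point-set sampler for one rigid body in its body frame
#'
#' Returns a `function(n)` drawing `n` independent points (rows of an
#' `n x 3` matrix) from the scatterer or reference-point distribution of a
#' rigid sub-unit.
#'
#' @param shape one of `"ball"`, `"sphere_surface"`, `"shell_volume"`,
#'   `"rod"`, `"circle"`, `"disk_area"`, `"disk_rim"`,
#'   `"cylinder_volume"`, `"cylinder_hull"`, `"cylinder_ends"`,
#'   `"cylinder_surface"`, `"point"`.
#' @param R,L,Ri,Ro dimensions (lengths) as required by the shape.
#' @return a sampler `function(n)`.
#' @export
point_sampler <- function(shape, R = NULL, L = NULL, Ri = NULL, Ro = NULL) {
  switch(shape,
    ball = function(n) R * runif(n)^(1 / 3) * runit_vec(n),
    sphere_surface = function(n) R * runit_vec(n),
    shell_volume = function(n) {
      r <- (runif(n) * (Ro^3 - Ri^3) + Ri^3)^(1 / 3)
      r * runit_vec(n)
    },
    rod = function(n) cbind(0, 0, runif(n, -L / 2, L / 2)),
    circle = function(n) {
      th <- runif(n, 0, 2 * pi)
      cbind(R * cos(th), R * sin(th), 0)
    },
    disk_area = function(n) {
      r <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th), 0)
    },
    disk_rim = function(n) {
      th <- runif(n, 0, 2 * pi)
      cbind(R * cos(th), R * sin(th), 0)
    },
    cylinder_volume = function(n) {
      r <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th), runif(n, -L / 2, L / 2))
    },
    cylinder_hull = function(n) {
      th <- runif(n, 0, 2 * pi)
      cbind(R * cos(th), R * sin(th), runif(n, -L / 2, L / 2))
    },
    cylinder_ends = function(n) {
      r <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th), sample(c(-1, 1), n, TRUE) * L / 2)
    },
    cylinder_surface = {
      # area-weighted union of hull (2 pi R L) and both end disks (2 pi R^2)
      hull <- point_sampler("cylinder_hull", R = R, L = L)
      ends <- point_sampler("cylinder_ends", R = R, L = L)
      function(n) {
        from_hull <- runif(n) < L / (L + R)
        out <- matrix(0, n, 3)
        if (any(from_hull)) out[from_hull, ] <- hull(sum(from_hull))
        if (any(!from_hull)) out[!from_hull, ] <- ends(sum(!from_hull))
        out
      }
    },
    point = function(n) matrix(0, n, 3),
    stop("unknown sampler shape: ", shape))
}

#' Monte Carlo estimate of a pair-distance factor
#'
#' Estimates `mean(sinc(q * |p1 - p2|))` over `n_pairs` independent draws
#' from two point-set samplers of one rigid sub-unit in its body frame.
#' This realizes the defining averages of the sub-unit factors for any pair
#' of distributions and is the oracle used to validate the closed forms.
#'
#' @param sampler1,sampler2 `function(n)` returning `n x 3` point matrices,
#'   e.g. from [point_sampler()].
#' @param q numeric vector of non-negative momentum transfers.
#' @param n_pairs number of independent pairs (>= 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return data.frame with columns `q`, `value`, `stderr`.
#' @export
numeric_factor_mc <- function(sampler1, sampler2, q, n_pairs = 10000L,
                              seed = 2024L) {
  if (any(q < 0)) stop("q must be non-negative")
  if (n_pairs < 1000L) stop("n_pairs must be at least 1000")
  d <- with_seed(seed, {
    p1 <- sampler1(n_pairs)
    p2 <- sampler2(n_pairs)
    sqrt(rowSums((p1 - p2)^2))
  })
  val <- numeric(length(q)); se <- numeric(length(q))
  for (i in seq_along(q)) {
    s <- sk_sinc(q[i] * d)
    val[i] <- mean(s)
    se[i] <- stats::sd(s) / sqrt(n_pairs)
  }
  data.frame(q = q, value = val, stderr = se)
}

# ---- numeric-tier registry --------------------------------------------------

.sk_mc <- new.env(parent = emptyenv())

reg_mc <- function(key, params, make) {
  assign(key, list(params = params, make = make), envir = .sk_mc)
}

register_mc_samplers <- function() {
  reg_mc("ThinDisk|rim_area", "R", function(p)
    list(point_sampler("disk_rim", R = p[1]),
         point_sampler("disk_area", R = p[1])))
  cylshapes <- c(hull = "cylinder_hull", ends = "cylinder_ends",
                 surface = "cylinder_surface", center = "point",
                 volume = "cylinder_volume")
  refs <- c("hull", "ends", "surface")
  for (r in refs) {
    local({
      rr <- r
      reg_mc(paste0("SolidCylinder|", rr, "_volume"), c("R", "L"),
             function(p) list(
               point_sampler(cylshapes[[rr]], R = p[1], L = p[2]),
               point_sampler("cylinder_volume", R = p[1], L = p[2])))
      reg_mc(paste0("SolidCylinder|center_", rr), c("R", "L"),
             function(p) list(
               point_sampler("point"),
               point_sampler(cylshapes[[rr]], R = p[1], L = p[2])))
    })
  }
  prs <- expand.grid(a = refs, b = refs, stringsAsFactors = FALSE)
  prs <- prs[prs$a <= prs$b, ]
  for (i in seq_len(nrow(prs))) {
    local({
      a <- prs$a[i]; b <- prs$b[i]
      reg_mc(paste0("SolidCylinder|", a, "_", b), c("R", "L"),
             function(p) list(
               point_sampler(cylshapes[[a]], R = p[1], L = p[2]),
               point_sampler(cylshapes[[b]], R = p[1], L = p[2])))
    })
  }
  # numeric-tier evaluator hooks
  reg_fun("MCFACTOR", mcfactor_eval, NULL)
  reg_fun("MCQ2", mcq2_eval, NULL)
  invisible(NULL)
}

mcfactor_call <- function(key, psyms) {
  as.call(c(as.name("MCFACTOR"), key, Q, unname(psyms)))
}

mc_distances <- function(key, pvals) {
  entry <- if (exists(key, envir = .sk_mc, inherits = FALSE))
    get(key, envir = .sk_mc) else stop("unknown Monte Carlo factor: ", key)
  ck <- paste(key, paste(signif(pvals, 12), collapse = ","))
  cache <- .sk$mc_cache
  if (!is.null(cache[[ck]])) return(cache[[ck]])
  sp <- entry$make(pvals)
  d <- with_seed(2024L, {
    n <- 65536L                     # 2^16 pairs, fixed default seed
    p1 <- sp[[1]](n); p2 <- sp[[2]](n)
    sqrt(rowSums((p1 - p2)^2))
  })
  cache[[ck]] <- d
  d
}

mcfactor_eval <- function(key, q, ...) {
  if (any(q < 0)) stop("q must be non-negative")
  d <- mc_distances(key, c(...))
  vapply(q, function(qi) mean(sk_sinc(qi * d)), numeric(1))
}

mcq2_eval <- function(key, ...) mean(mc_distances(key, c(...))^2)

# series of a numeric-tier factor: 1 - q^2 <r^2>/6 + (unavailable beyond)
mcfactor_series <- function(e, ord) {
  args <- as.list(e)[-1]
  out <- as.list(rep(0, ord + 1))
  out[[1]] <- 1
  if (ord >= 2)
    out[[3]] <- mk_prod(-1 / 6,
                        as.call(c(as.name("MCQ2"), args[[1]], args[-(1:2)])))
  if (ord >= 4)
    for (k in seq(5, ord + 1, by = 2)) out[[k]] <- quote(.INVALID)
  out
}
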