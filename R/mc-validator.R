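# Brute-force Monte Carlo oracle: samples explicit bead-model conformations
# of any built structure (completely flexible links, independent sub-unit
# orientations and conformations) and estimates the composite scattering by
# the orientationally averaged Debye double sum.  Used by the test suite to
# validate every symbolic result; O(n_beads^2) per conformation by design.

rand_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  u <- rnorm(4)
  u <- u / sqrt(sum(u^2))
  a <- u[1]; b <- u[2]; c <- u[3]; d <- u[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# flatten nested structure instances into leaf sub-units with full path
# names; link endpoint keys become "full:unit:name|ref[#label]".
flatten_scope <- function(w, scope, prefix = "") {
  units <- list()
  links <- list()
  fkey <- function(scope, unit, local, prefix) {
    u <- scope$units[[unit]]
    if (u$kind == "su") return(paste0(prefix, unit, "|", local))
    sl <- split_local(local)
    fkey(scope_of_type(w, u$type), sl$member, sl$rest,
         paste0(prefix, unit, ":"))
  }
  for (u in scope$units) {
    if (u$kind == "su") {
      units[[paste0(prefix, u$name)]] <-
        list(name = paste0(prefix, u$name), type = u$type, tag = u$tag)
    } else {
      inner <- flatten_scope(w, scope_of_type(w, u$type),
                             paste0(prefix, u$name, ":"))
      units <- c(units, inner$units)
      links <- c(links, inner$links)
    }
  }
  for (l in scope$links) {
    links[[length(links) + 1L]] <- list(
      a = fkey(scope, l$ua, local_of_key(l$a), prefix),
      b = fkey(scope, l$ub, local_of_key(l$b), prefix))
  }
  list(units = units, links = links)
}

unit_param <- function(params, stem, tag) {
  nm <- paste0(stem, "_", tag)
  if (!nm %in% names(params)) stop("missing parameter value: ", nm)
  as.numeric(params[[nm]])
}

# sample beads + realized reference coordinates for one leaf unit in its
# own (randomly oriented) frame
sample_unit <- function(type, tag, params, nbeads, needed_refs) {
  realize <- function(beads, pick) {
    out <- lapply(needed_refs, pick)
    names(out) <- needed_refs
    out
  }
  refname <- function(r) sub("#.*$", "", r)
  switch(type,
    GaussianPolymer = {
      # beads are iid uniform contour positions of the continuous chain,
      # realized jointly as a Gaussian walk over the sorted positions
      # (pairwise <r^2> = 6 Rg2 |s - t| exactly, so the distinct-pair
      # Debye estimator has no discretization bias)
      Rg2 <- unit_param(params, "Rg2", tag)
      stopifnot(nbeads >= 50L)
      ref_s <- vapply(needed_refs, function(r) switch(refname(r),
        end1 = 0, end2 = 1, middle = 0.5, contour = runif(1),
        stop("unknown polymer reference: ", r)), numeric(1))
      s <- c(ref_s, runif(nbeads))
      ord <- order(s)
      gaps <- diff(s[ord])
      pos <- matrix(0, length(s), 3)
      pos[ord, ] <- rbind(0, apply(matrix(rnorm(3 * length(gaps),
                                                sd = sqrt(2 * Rg2 *
                                                            rep(gaps, 3))),
                                          ncol = 3), 2, cumsum))
      refc <- setNames(lapply(seq_along(needed_refs),
                              function(i) pos[i, ]), needed_refs)
      list(beads = pos[length(ref_s) + seq_len(nbeads), , drop = FALSE],
           refc = refc)
    },
    GaussianLoop = {
      # Brownian-bridge ring sampled at iid uniform contour positions:
      # pairwise <r^2> = 12 Rg2 u(1 - u), u = contour separation
      Rg2 <- unit_param(params, "Rg2", tag)
      stopifnot(nbeads >= 50L)
      ref_s <- vapply(needed_refs, function(r) switch(refname(r),
        contour = runif(1),
        stop("unknown loop reference: ", r)), numeric(1))
      s <- c(ref_s, runif(nbeads))
      ord <- order(s)
      gaps <- diff(c(s[ord], 1 + s[ord][1]))  # close the ring
      walk <- rbind(0, apply(matrix(rnorm(3 * length(gaps),
                                          sd = sqrt(4 * Rg2 *
                                                      rep(gaps, 3))),
                                    ncol = 3), 2, cumsum))
      t_ord <- c(s[ord], 1 + s[ord][1]) - s[ord][1]
      bridge <- walk - outer(t_ord, walk[nrow(walk), ])
      pos <- matrix(0, length(s), 3)
      pos[ord, ] <- bridge[seq_along(s), ]
      refc <- setNames(lapply(seq_along(needed_refs),
                              function(i) pos[i, ]), needed_refs)
      list(beads = pos[length(ref_s) + seq_len(nbeads), , drop = FALSE],
           refc = refc)
    },
    ThinRod = {
      L <- unit_param(params, "L", tag)
      stopifnot(nbeads >= 50L)
      u <- drop(rand_rotation() %*% c(0, 0, 1))
      beads <- outer(runif(nbeads, -L / 2, L / 2), u)  # iid points on the rod
      refc <- realize(beads, function(r) switch(refname(r),
        end1 = -L / 2 * u, end2 = L / 2 * u, middle = c(0, 0, 0),
        contour = runif(1, -L / 2, L / 2) * u,
        stop("unknown rod reference: ", r)))
      list(beads = beads, refc = refc)
    },
    ThinCircle = {
      R <- unit_param(params, "R", tag)
      rot <- rand_rotation()
      th <- runif(nbeads, 0, 2 * pi)   # iid points on the circle
      beads <- cbind(R * cos(th), R * sin(th), 0) %*% t(rot)
      refc <- realize(beads, function(r) switch(refname(r),
        center = c(0, 0, 0),
        contour = { a <- runif(1, 0, 2 * pi)
                    drop(rot %*% c(R * cos(a), R * sin(a), 0)) },
        stop("unknown circle reference: ", r)))
      list(beads = beads, refc = refc)
    },
    SolidSphere = ,
    ThinSphericalShell = {
      R <- unit_param(params, "R", tag)
      beads <- if (type == "SolidSphere")
        point_sampler("ball", R = R)(nbeads)
      else point_sampler("sphere_surface", R = R)(nbeads)
      refc <- realize(beads, function(r) switch(refname(r),
        center = c(0, 0, 0),
        surface = R * drop(runit_vec(1)),
        stop("unknown sphere reference: ", r)))
      list(beads = beads, refc = refc)
    },
    SolidSphericalShell = {
      Ri <- unit_param(params, "Ri", tag)
      Ro <- unit_param(params, "Ro", tag)
      beads <- point_sampler("shell_volume", Ri = Ri, Ro = Ro)(nbeads)
      refc <- realize(beads, function(r) switch(refname(r),
        center = c(0, 0, 0),
        surfacei = Ri * drop(runit_vec(1)),
        surfaceo = Ro * drop(runit_vec(1)),
        surface = {
          rr <- if (runif(1) < Ri^2 / (Ri^2 + Ro^2)) Ri else Ro
          rr * drop(runit_vec(1))
        },
        stop("unknown shell reference: ", r)))
      list(beads = beads, refc = refc)
    },
    ThinDisk = {
      R <- unit_param(params, "R", tag)
      rot <- rand_rotation()
      beads <- point_sampler("disk_area", R = R)(nbeads) %*% t(rot)
      refc <- realize(beads, function(r) switch(refname(r),
        center = c(0, 0, 0),
        surface = drop(rot %*% point_sampler("disk_area", R = R)(1)[1, ]),
        rim = drop(rot %*% point_sampler("disk_rim", R = R)(1)[1, ]),
        stop("unknown disk reference: ", r)))
      list(beads = beads, refc = refc)
    },
    SolidCylinder = {
      R <- unit_param(params, "R", tag)
      L <- unit_param(params, "L", tag)
      rot <- rand_rotation()
      beads <- point_sampler("cylinder_volume", R = R, L = L)(nbeads) %*% t(rot)
      refc <- realize(beads, function(r) {
        shape <- switch(refname(r), center = "point", hull = "cylinder_hull",
                        ends = "cylinder_ends", surface = "cylinder_surface",
                        stop("unknown cylinder reference: ", r))
        drop(rot %*% point_sampler(shape, R = R, L = L)(1)[1, ])
      })
      list(beads = beads, refc = refc)
    },
    Point = {
      refc <- realize(NULL, function(r) c(0, 0, 0))
      list(beads = matrix(numeric(0), 0, 3), refc = refc)
    },
    stop("no conformation sampler for type ", type))
}

#' Sample one explicit bead-model conformation of a structure
#'
#' Realizes every sub-unit as a point cloud in 3-d space: Gaussian polymers
#' as discrete random walks, loops as Brownian bridges, rigid bodies as
#' uniformly sampled point sets with independent random orientations, and
#' places them so that each link's two realized reference points coincide
#' exactly.  Distributed reference points are redrawn on every call.
#'
#' @param w an `sk_world`.
#' @param structure_name structure type, unit name or graph id.
#' @param params named numeric vector of structural parameters
#'   (`Rg2_<tag>`, `L_<tag>`, ...).
#' @param beads_per_unit discretization (>= 50 for chain types).
#' @param seed optional integer seed for a reproducible conformation.
#' @return a list with per-unit bead matrices (`units`), realized link
#'   coordinates (`refs`) and the stacked coordinate matrix `X`.
#' @export
sample_conformation <- function(w, structure_name, params,
                                beads_per_unit = 200L, seed = NULL) {
  stopifnot(inherits(w, "sk_world"))
  if (!is.null(seed)) set.seed(seed)
  flat <- flatten_scope(w, structure_scope(w, structure_name))
  sample_conformation_flat(flat, params, beads_per_unit)
}

sample_conformation_flat <- function(flat, params, beads_per_unit) {
  needed <- lapply(flat$units, function(u) character(0))
  for (l in flat$links) {
    for (k in c(l$a, l$b)) {
      un <- sub("\\|.*$", "", k)
      needed[[un]] <- union(needed[[un]], local_of_key(k))
    }
  }
  conf <- list()
  for (u in flat$units)
    conf[[u$name]] <- sample_unit(u$type, u$tag, params, beads_per_unit,
                                  needed[[u$name]])
  # assemble: translate each newly attached unit so link points coincide
  placed <- setNames(logical(length(flat$units)), names(flat$units))
  placed[[1]] <- TRUE
  adj <- lapply(flat$units, function(u) list())
  for (l in flat$links) {
    ua <- sub("\\|.*$", "", l$a); ub <- sub("\\|.*$", "", l$b)
    adj[[ua]] <- c(adj[[ua]], list(list(to = ub, my = local_of_key(l$a),
                                        other = local_of_key(l$b))))
    adj[[ub]] <- c(adj[[ub]], list(list(to = ua, my = local_of_key(l$b),
                                        other = local_of_key(l$a))))
  }
  queue <- names(flat$units)[1]
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (e in adj[[u]]) {
      if (placed[[e$to]]) next
      off <- conf[[u]]$refc[[e$my]] - conf[[e$to]]$refc[[e$other]]
      conf[[e$to]]$beads <- sweep(conf[[e$to]]$beads, 2, off, `+`)
      conf[[e$to]]$refc <- lapply(conf[[e$to]]$refc, function(p) p + off)
      placed[[e$to]] <- TRUE
      queue <- c(queue, e$to)
    }
  }
  if (!all(placed)) stop("structure is not connected")
  refs <- list()
  for (un in names(conf))
    for (rn in names(conf[[un]]$refc))
      refs[[paste0(un, "|", rn)]] <- conf[[un]]$refc[[rn]]
  X <- do.call(rbind, lapply(conf, `[[`, "beads"))
  list(units = conf, refs = refs, X = X, flat = flat)
}

#' Monte Carlo Debye-sum estimate of a composite scattering curve
#'
#' Averages the normalized orientationally averaged Debye double sum
#' `sum_ij beta_i beta_j sinc(q r_ij) / (sum beta)^2` over independently
#' sampled conformations.  This is the independent numerical oracle for
#' every symbolic form factor.
#'
#' @param w an `sk_world`.
#' @param structure_name structure type, unit name or graph id.
#' @param grid numeric q vector.
#' @param n_conformations number of conformations (>= 2 for a standard
#'   error).
#' @param params named numeric vector: structural parameters and the
#'   `beta_<tag>` contrasts.
#' @param beads_per_unit beads per sub-unit (>= 50 for chain types).
#' @param seed integer seed; identical seeds give identical curves.
#' @return an `sk_curve` with columns `q`, `I`, `stderr`.
#' @export
debye_estimate <- function(w, structure_name, grid, n_conformations = 1000L,
                           params = numeric(), beads_per_unit = 100L,
                           seed = 1L) {
  stopifnot(inherits(w, "sk_world"))
  if (n_conformations < 2L)
    stop("need at least 2 conformations for a standard error")
  q <- as.numeric(grid)
  flat <- flatten_scope(w, structure_scope(w, structure_name))
  betas <- vapply(flat$units, function(u) {
    bf <- subunit_type(u$type)$beta_fixed
    if (!is.null(bf)) bf else unit_param(params, "beta", u$tag)
  }, numeric(1))
  btot <- sum(betas)
  if (btot == 0) stop("total excess scattering length is zero")
  acc <- numeric(length(q)); acc2 <- numeric(length(q))
  with_seed(seed, {
    # every sub-unit is sampled as an iid point set of its continuous
    # scatterer distribution (chains via iid contour positions), so the
    # within-unit distinct-pair average is unbiased for the continuous
    # body and the estimator carries no discretization bias
    for (it in seq_len(n_conformations)) {
      cf <- sample_conformation_flat(flat, params, beads_per_unit)
      nb <- vapply(cf$units, function(u) nrow(u$beads), integer(1))
      wts <- rep(betas / pmax(nb, 1L), nb)
      uid <- rep(seq_along(nb) - 1L, nb)
      mult <- ifelse(nb > 1L, nb / (nb - 1), 1)
      v <- debye_sum_cpp(cf$X, wts, as.integer(uid), mult, q) / btot^2
      acc <- acc + v
      acc2 <- acc2 + v^2
    }
  })
  m <- acc / n_conformations
  va <- pmax(acc2 / n_conformations - m^2, 0)
  se <- sqrt(va / (n_conformations - 1L))
  cv <- new_curve(q, m, stderr = se)
  attr(cv, "params") <- params
  cv
}

#' Compare an analytic curve with a Monte Carlo estimate
#'
#' Per-q z-scores of the analytic values against the Monte Carlo mean and
#' standard error; the conventional acceptance is `max |z| < 3` (note that
#' with many q points an occasional excursion slightly above 3 is expected
#' unless a Bonferroni-style allowance is made).
#'
#' @param analytic an `sk_curve` (no stderr needed).
#' @param mc an `sk_curve` with a `stderr` column, on the same grid.
#' @param z_max acceptance threshold for `max |z|`.
#' @return list with `z`, `max_z` and logical `pass`.
#' @export
compare_curves <- function(analytic, mc, z_max = 3) {
  if (!isTRUE(all.equal(analytic$q, mc$q)))
    stop("curves are on different q grids")
  if (!"stderr" %in% names(mc)) stop("mc curve has no stderr column")
  z <- (analytic$I - mc$I) / mc$stderr
  exact <- mc$stderr == 0 & abs(analytic$I - mc$I) < 1e-12
  z[exact] <- 0
  list(z = z, max_z = max(abs(z)), pass = max(abs(z)) < z_max)
}
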