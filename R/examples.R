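# Ready-made example structures: the classic composite models that double
# as test fixtures (diblock, micelle, decorated polymer, N-unit chains,
# dendrimers, hierarchical chain of diblock stars).

#' Build a diblock copolymer
#'
#' Two Gaussian polymers linked end2-to-end1 and wrapped as a structure
#' type.
#'
#' @param w world to build in (a fresh one by default).
#' @param name structure type name.
#' @param tags tags of the two blocks.
#' @return list with the `world` and the structure `name`.
#' @export
build_diblock <- function(w = sk_world(), name = "DiBlockCopolymer",
                          tags = c("A", "B")) {
  add_unit(w, "GaussianPolymer", "A", tag = tags[1])
  gid <- link_unit(w, "GaussianPolymer", "B.end1", "A.end2", tag = tags[2])
  wrap_structure(w, gid, name)
  list(world = w, name = name)
}

#' Build a block-copolymer micelle
#'
#' `n_arms` Gaussian polymers (tag "p") grafted by end1 to distinct random
#' points on the surface of a solid sphere core (tag "s").
#'
#' @param w world to build in.
#' @param n_arms number of grafted chains.
#' @param name structure type name.
#' @return list with the `world` and the structure `name`.
#' @export
build_micelle <- function(w = sk_world(), n_arms = 3L, name = "Micelle") {
  gid <- add_unit(w, "SolidSphere", "core", tag = "s")
  for (i in seq_len(n_arms))
    gid <- link_unit(w, "GaussianPolymer",
                     sprintf("arm%d.end1", i),
                     sprintf("core.surface#p%d", i), tag = "p")
  wrap_structure(w, gid, name)
  list(world = w, name = name)
}

#' Build a decorated polymer (beads on a string)
#'
#' `n_beads` solid spheres (tag "s") linked by their centers to distinct
#' random contour points of one Gaussian polymer (tag "p").
#'
#' @param w world to build in.
#' @param n_beads number of decorating spheres.
#' @param name structure type name.
#' @return list with the `world` and the structure `name`.
#' @export
build_decorated_polymer <- function(w = sk_world(), n_beads = 3L,
                                    name = "DecoratedPolymer") {
  gid <- add_unit(w, "GaussianPolymer", "backbone", tag = "p")
  for (i in seq_len(n_beads))
    gid <- link_unit(w, "SolidSphere",
                     sprintf("bead%d.center", i),
                     sprintf("backbone.contour#r%d", i), tag = "s")
  wrap_structure(w, gid, name)
  list(world = w, name = name)
}

#' Build a linear chain of identical sub-units
#'
#' `n` identically tagged sub-units linked into a chain, either end-to-end
#' (`linkage = "end"`, polymer/rod types) or contour-to-contour
#' (`linkage = "contour"`, any type with a contour).
#'
#' @param w world to build in.
#' @param n chain length.
#' @param type sub-unit type.
#' @param linkage `"end"` or `"contour"`.
#' @param tag shared tag.
#' @param name structure type name.
#' @return list with the `world` and the structure `name`.
#' @export
build_chain <- function(w = sk_world(), n = 100L, type = "GaussianPolymer",
                        linkage = c("end", "contour"), tag = "p",
                        name = "Chain") {
  linkage <- match.arg(linkage)
  gid <- add_unit(w, type, "P1", tag = tag)
  if (n > 1L) for (i in 2:n) {
    refs <- if (linkage == "end")
      c(sprintf("P%d.end1", i), sprintf("P%d.end2", i - 1L))
    else
      c(sprintf("P%d.contour#r%d", i, i), sprintf("P%d.contour#s%d", i - 1L, i))
    gid <- link_unit(w, type, refs[1], refs[2], tag = tag)
  }
  wrap_structure(w, gid, name)
  list(world = w, name = name)
}

#' Build a dendrimer
#'
#' Seeds an invisible Point sub-unit and recursively grafts `generations`
#' generations of arms: `functionality` arms on the seed, then
#' `functionality - 1` on each tip, so every junction has the stated
#' functionality.
#'
#' @param w world to build in.
#' @param generations number of generations.
#' @param functionality junction functionality.
#' @param type arm sub-unit type (`"GaussianPolymer"` or `"ThinRod"`).
#' @param linkage `"end"` (end1 grafted to previous tip) or `"contour"`.
#' @param tag shared arm tag.
#' @param name structure type name.
#' @return list with the `world`, the structure `name` and
#'   `units_per_generation`.
#' @export
build_dendrimer <- function(w = sk_world(), generations = 4L,
                            functionality = 3L, type = "GaussianPolymer",
                            linkage = c("end", "contour"), tag = "p",
                            name = "Dendrimer") {
  linkage <- match.arg(linkage)
  add_unit(w, "Point", "center")
  counter <- 0L
  per_gen <- integer(generations)
  gid <- NULL
  attach_gen <- function(g, f, ref) {
    n_arms <- if (identical(ref, "center.point")) f else f - 1L
    for (a in seq_len(n_arms)) {
      counter <<- counter + 1L
      nm <- sprintf("S%d", counter)
      newref <- if (linkage == "end") sprintf("%s.end1", nm)
                else sprintf("%s.contour#g%d", nm, counter)
      gid <<- link_unit(w, type, newref, ref, tag = tag)
      per_gen[generations - g + 1L] <<- per_gen[generations - g + 1L] + 1L
      tipref <- if (linkage == "end") sprintf("%s.end2", nm)
                else sprintf("%s.contour#t%d", nm, counter)
      if (g > 1L) attach_gen(g - 1L, f, tipref)
    }
  }
  attach_gen(generations, functionality, "center.point")
  wrap_structure(w, gid, name)
  list(world = w, name = name, units_per_generation = per_gen)
}

#' Build a hierarchical chain of diblock stars
#'
#' The canonical hierarchical example: a diblock copolymer (polyA + polyB)
#' is wrapped as a type; four diblocks joined at their polyA.end1 points
#' form a star; five stars linked tip-to-tip (diblock1:polyB.end2 to the
#' previous star's diblock3:polyB.end2) form a chain of 5 x 4 x 2 = 40
#' leaf sub-units, built and derived entirely through the hierarchy.
#'
#' @param w world to build in.
#' @param n_stars number of stars in the chain.
#' @param tags tags of the inner (A) and outer (B) blocks.
#' @return list with the `world` and the names of the `diblock`, `star`
#'   and `chain` types.
#' @export
build_star_chain <- function(w = sk_world(), n_stars = 5L,
                             tags = c("pA", "pB")) {
  add_unit(w, "GaussianPolymer", "polyA", tag = tags[1])
  g <- link_unit(w, "GaussianPolymer", "polyB.end1", "polyA.end2",
                 tag = tags[2])
  wrap_structure(w, g, "diblock")
  s <- add_unit(w, "diblock", "diblock1")
  for (i in 2:4)
    s <- link_unit(w, "diblock", sprintf("diblock%d:polyA.end1", i),
                   "diblock1:polyA.end1")
  wrap_structure(w, s, "star")
  cg <- add_unit(w, "star", "star1")
  if (n_stars > 1L) for (i in 2:n_stars)
    cg <- link_unit(w, "star", sprintf("star%d:diblock1:polyB.end2", i),
                    sprintf("star%d:diblock3:polyB.end2", i - 1L))
  wrap_structure(w, cg, "chain")
  list(world = w, diblock = "diblock", star = "star", chain = "chain")
}
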