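# The world: named sub-unit instances, links at reference points, and
# named structure types.  Structures are trees by construction: a link is
# only created together with the new unit it attaches, so no cycle can ever
# be formed (completely flexible links, non-interacting sub-units and
# acyclic connectivity are the assumptions under which the composite
# scattering factorizes over sub-units).

#' Create an empty world
#'
#' A world hosts uniquely named sub-unit instances, the links between their
#' reference points, and wrapped structure types.
#'
#' @return an object of class `sk_world`.
#' @export
#' @examples
#' w <- sk_world()
#' add_unit(w, "GaussianPolymer", "A")
#' link_unit(w, "GaussianPolymer", "B.end1", "A.end2")
sk_world <- function() {
  w <- new.env(parent = emptyenv())
  w$units <- list()
  w$links <- list()
  w$graphs <- list()
  w$next_graph <- 1L
  w$stypes <- list()
  w$cache <- new.env(parent = emptyenv())
  class(w) <- "sk_world"
  w
}

#' @export
print.sk_world <- function(x, ...) {
  live <- Filter(function(u) !u$frozen, x$units)
  cat("<world>", length(live), "live unit(s),",
      length(x$stypes), "structure type(s)\n")
  invisible(x)
}

check_name <- function(name, what = "name") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop(what, " must be a non-empty string")
  if (grepl("[.:#|]", name))
    stop(what, " '", name, "' may not contain '.', ':', '#' or '|'")
  name
}

name_taken <- function(w, name)
  name %in% names(w$units) || name %in% names(w$stypes)

# ---- reference addresses ----------------------------------------------------
# An address is  struct:sub...:unit.refpoint[#label] ; the final component
# names a reference point on a sub-unit, optionally realized by a label.

split_addr <- function(addr) {
  stopifnot(is.character(addr), length(addr) == 1L)
  segs <- strsplit(addr, ":", fixed = TRUE)[[1]]
  if (!length(segs) || any(!nzchar(segs)))
    stop("malformed reference address: '", addr, "'")
  last <- segs[length(segs)]
  m <- regmatches(last, regexec("^([^.#]+)\\.([^.#]+)(#([^.#]+))?$", last))[[1]]
  if (!length(m))
    stop("malformed reference address segment: '", last,
         "' (expected unit.refpoint or unit.refpoint#label)")
  list(path = segs[-length(segs)], unit = m[2], ref = m[3],
       label = if (nzchar(m[4])) m[5] else NULL)
}

# local reference string relative to a top-level member of a scope
local_ref_string <- function(parts, from = 1L) {
  segs <- parts$path
  tail_txt <- paste0(parts$unit, ".", parts$ref,
                     if (!is.null(parts$label)) paste0("#", parts$label) else "")
  paste(c(segs[seq_along(segs)[seq_along(segs) >= from]], tail_txt),
        collapse = ":")
}

# scope: the unit/link list of either a live graph or a structure type
scope_of_graph <- function(w, gid) {
  g <- w$graphs[[as.character(gid)]]
  if (is.null(g)) stop("unknown graph id: ", gid)
  list(units = w$units[g$units],
       links = Filter(function(l) l$ua %in% g$units, w$links))
}

scope_of_type <- function(w, tname) {
  st <- w$stypes[[tname]]
  if (is.null(st)) stop("unknown structure type: ", tname)
  list(units = st$units, links = st$links)
}

# split a local reference string "member.ref[#label]" or "member:deeper..."
# into its first component and the remainder
split_local <- function(local) {
  segs <- strsplit(local, ":", fixed = TRUE)[[1]]
  if (!length(segs) || any(!nzchar(segs)))
    stop("malformed reference '", local, "'")
  if (length(segs) == 1L) {
    if (!grepl(".", segs[1], fixed = TRUE))
      stop("malformed reference '", local,
           "': expected member.refpoint[#label]")
    member <- sub("\\..*$", "", segs[1])
    rest <- sub("^[^.]+\\.", "", segs[1])
  } else {
    if (grepl("[.#]", segs[1]))
      stop("malformed reference '", local,
           "': structure member '", segs[1], "' may not carry '.' or '#'")
    member <- segs[1]
    rest <- paste(segs[-1], collapse = ":")
  }
  list(member = member, rest = rest)
}

# validate that `local` (a ref string relative to `unit`) resolves within the
# world; returns the canonical realized-point key "unit|local".
validate_local_ref <- function(w, scope, unit_name, local,
                               require_label = TRUE) {
  u <- scope$units[[unit_name]]
  if (is.null(u))
    stop("no unit named '", unit_name, "' at this structure level")
  if (u$kind == "su") {
    m <- regmatches(local, regexec("^([^.#:]+)(#([^.#:]+))?$", local))[[1]]
    if (!length(m))
      stop("malformed reference '", local, "' on sub-unit '", unit_name, "'")
    ref <- m[2]; label <- if (nzchar(m[3])) m[4] else NULL
    type <- subunit_type(u$type)
    if (!ref %in% names(type$refs))
      stop("unknown reference point '", ref, "' on '", unit_name,
           "' of type ", u$type,
           " (has: ", paste(names(type$refs), collapse = ", "), ")")
    kind <- type$refs[[ref]]
    if (kind == "specific" && !is.null(label))
      stop("reference point '", ref, "' on '", unit_name,
           "' is specific and takes no '#' label")
    if (kind == "distributed" && is.null(label) && require_label)
      stop("reference point '", ref, "' on '", unit_name,
           "' is distributed; realize it with a '#' label, e.g. '",
           unit_name, ".", ref, "#r1'")
  } else {
    sl <- split_local(local)
    inner_scope <- scope_of_type(w, u$type)
    validate_local_ref(w, inner_scope, sl$member, sl$rest, require_label)
  }
  paste0(unit_name, "|", local)
}

#' Resolve a reference address
#'
#' Maps a textual path (through nested structure instances down to a
#' reference point) to the realized point it denotes.  The first path
#' component may be a live unit, or a structure type name whose template is
#' then descended.
#'
#' @param w an `sk_world`.
#' @param address address string, e.g. `"A.end1"` or
#'   `"chain:star3:diblock1:polyA.end1"`.
#' @return a list with the owning scope, top-level unit and local reference.
#' @export
resolve_ref <- function(w, address) {
  parts <- split_addr(address)   # syntax check up front
  if (length(parts$path) && parts$path[1] %in% names(w$stypes)) {
    tname <- parts$path[1]
    scope <- scope_of_type(w, tname)
    sl <- split_local(local_ref_string(parts, from = 2L))
    key <- validate_local_ref(w, scope, sl$member, sl$rest)
    return(list(root = tname, scope = scope, unit = sl$member,
                local = sl$rest, key = key, address = address))
  }
  sl <- split_local(local_ref_string(parts, from = 1L))
  u <- w$units[[sl$member]]
  if (is.null(u))
    stop("cannot resolve '", address, "': no unit or structure type named '",
         sl$member, "'")
  scope <- scope_of_graph(w, u$graph)
  key <- validate_local_ref(w, scope, sl$member, sl$rest)
  list(root = u$graph, scope = scope, unit = sl$member, local = sl$rest,
       key = key, address = address)
}

# ---- building ---------------------------------------------------------------

new_unit_record <- function(name, type, tag, kind, graph)
  list(name = name, type = type, tag = if (is.null(tag)) name else tag,
       kind = kind, graph = graph, frozen = FALSE)

unit_kind_of <- function(w, type) {
  if (is_subunit_type(type)) return("su")
  if (type %in% names(w$stypes)) return("st")
  stop("unknown type: '", type,
       "' is neither a sub-unit type nor a wrapped structure type")
}

#' Add a new, unlinked unit to the world
#'
#' @param w an `sk_world`.
#' @param type a sub-unit type name (see [subunit_types()]) or the name of a
#'   wrapped structure type.
#' @param name unique unit name (case sensitive).
#' @param tag optional tag; tagged units share parameter and contrast
#'   symbols (`Rg2_p`, `beta_p`, ...).  Defaults to the unit name.
#' @return the graph id of the new single-unit graph.
#' @export
add_unit <- function(w, type, name, tag = NULL) {
  stopifnot(inherits(w, "sk_world"))
  check_name(name, "unit name")
  if (!is.null(tag)) check_name(tag, "tag")
  if (name_taken(w, name)) stop("duplicate name: '", name, "' already exists")
  kind <- unit_kind_of(w, type)
  gid <- w$next_graph
  w$next_graph <- gid + 1L
  w$graphs[[as.character(gid)]] <- list(units = name, frozen = FALSE)
  w$units[[name]] <- new_unit_record(name, type, tag, kind, gid)
  gid
}

#' Add a new unit and link it to an existing reference point
#'
#' The new unit is attached by one of its reference points to a realized
#' reference point already in the world; because exactly one side of every
#' link is new, structures are acyclic by construction.
#'
#' @param w an `sk_world`.
#' @param type sub-unit type or structure type of the new unit.
#' @param new_ref the new unit's name and reference point, e.g. `"B.end1"`
#'   or, for a structure instance, `"star2:diblock1:polyB.end2"`.
#' @param existing_ref address of the existing reference point,
#'   e.g. `"A.end2"` or `"shell.surfaceo#p1"`.
#' @param tag optional tag (see [add_unit()]).
#' @return the graph id of the grown graph.
#' @export
link_unit <- function(w, type, new_ref, existing_ref, tag = NULL) {
  stopifnot(inherits(w, "sk_world"))
  kind <- unit_kind_of(w, type)
  sl <- split_local(new_ref)
  new_name <- sl$member
  new_local <- sl$rest
  check_name(new_name, "unit name")
  if (name_taken(w, new_name))
    stop("duplicate name: '", new_name, "' already exists")
  ex <- resolve_ref(w, existing_ref)
  if (is.character(ex$root))
    stop("cannot link to '", existing_ref,
         "': it lies inside the wrapped structure type '", ex$root,
         "', which is frozen")
  exu <- w$units[[ex$unit]]
  if (exu$frozen)
    stop("cannot link to '", existing_ref, "': its graph was wrapped into ",
         "a structure type and is frozen")
  gid <- exu$graph
  w$units[[new_name]] <- new_unit_record(new_name, type, tag, kind, gid)
  g <- w$graphs[[as.character(gid)]]
  g$units <- c(g$units, new_name)
  w$graphs[[as.character(gid)]] <- g
  scope <- scope_of_graph(w, gid)
  akey <- tryCatch(validate_local_ref(w, scope, new_name, new_local),
                   error = function(e) {
                     # roll back the half-added unit before failing
                     w$units[[new_name]] <- NULL
                     g$units <- setdiff(g$units, new_name)
                     w$graphs[[as.character(gid)]] <- g
                     stop(e)
                   })
  w$links[[length(w$links) + 1L]] <-
    list(ua = new_name, a = akey, ub = ex$unit, b = ex$key)
  gid
}

#' Wrap a graph into a reusable structure type
#'
#' Freezes the graph: its composite form factor, amplitudes and phase
#' factors become available under the type name, and instances of the type
#' can be added and linked like sub-units.  Wrapped graphs are immutable.
#'
#' @param w an `sk_world`.
#' @param graph_id a graph id returned by [add_unit()]/[link_unit()].
#' @param structure_type_name unique name for the new type.
#' @return the structure type name, invisibly.
#' @export
wrap_structure <- function(w, graph_id, structure_type_name) {
  stopifnot(inherits(w, "sk_world"))
  check_name(structure_type_name, "structure type name")
  if (name_taken(w, structure_type_name))
    stop("duplicate name: '", structure_type_name, "' already exists")
  g <- w$graphs[[as.character(graph_id)]]
  if (is.null(g)) stop("unknown graph id: ", graph_id)
  if (g$frozen)
    stop("graph ", graph_id, " is already wrapped and immutable")
  if (!length(g$units)) stop("cannot wrap an empty graph")
  scope <- scope_of_graph(w, graph_id)
  w$stypes[[structure_type_name]] <-
    list(name = structure_type_name, units = scope$units,
         links = scope$links)
  g$frozen <- TRUE
  w$graphs[[as.character(graph_id)]] <- g
  for (un in g$units) w$units[[un]]$frozen <- TRUE
  invisible(structure_type_name)
}

# every graph must be a tree: connected with exactly n-1 links
validate_world <- function(w) {
  for (gid in names(w$graphs)) {
    sc <- scope_of_graph(w, gid)
    n <- length(sc$units)
    if (length(sc$links) != n - 1L)
      stop("graph ", gid, " is not a tree: ", n, " units but ",
           length(sc$links), " links")
    if (n > 1L) {
      adj <- scope_adjacency(sc)
      seen <- bfs_tree(adj, names(sc$units)[1])$order
      if (length(seen) != n) stop("graph ", gid, " is not connected")
    }
  }
  invisible(TRUE)
}
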