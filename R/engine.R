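# Composite scattering assembly.  The form factor of a structure is a
# double sum over sub-units: each unit contributes beta^2 F once, and each
# ordered pair contributes beta_I beta_J A_I (prod of Psi along the unique
# tree path) A_J; the I,J and J,I paths give identical terms, so unordered
# pairs are enumerated with an explicit factor 2.  Amplitudes and phase
# factors of the composite follow the same path logic.  Structure instances
# are handled by recursion: their own composite F, A and Psi (cached per
# type) stand in for the sub-unit factors.

scope_adjacency <- function(scope) {
  adj <- lapply(scope$units, function(u) list())
  for (i in seq_along(scope$links)) {
    l <- scope$links[[i]]
    adj[[l$ua]] <- c(adj[[l$ua]], list(list(to = l$ub, my = l$a, other = l$b)))
    adj[[l$ub]] <- c(adj[[l$ub]], list(list(to = l$ua, my = l$b, other = l$a)))
  }
  adj
}

bfs_tree <- function(adj, root) {
  parent <- setNames(rep(NA_character_, length(adj)), names(adj))
  pedge <- setNames(vector("list", length(adj)), names(adj))
  order <- character(0)
  queue <- root
  seen <- setNames(logical(length(adj)), names(adj))
  seen[root] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    order <- c(order, u)
    for (e in adj[[u]]) {
      if (!seen[[e$to]]) {
        seen[[e$to]] <- TRUE
        parent[[e$to]] <- u
        # edge stored from child's perspective: child's ref, parent's ref
        pedge[[e$to]] <- list(my = e$other, other = e$my)
        queue <- c(queue, e$to)
      }
    }
  }
  # precomputed root-ward ancestor chains (unit itself first)
  anc <- setNames(vector("list", length(adj)), names(adj))
  for (u in order)
    anc[[u]] <- c(u, if (!is.na(parent[[u]])) anc[[parent[[u]]]])
  list(parent = parent, pedge = pedge, order = order, anc = anc)
}

# path between two units in the tree: list(units, refs) where refs[[k]] is
# the (entry, exit) realized-point keys of units[[k]]; entry of the first
# and exit of the last are NA.
tree_path <- function(bt, from, to) {
  ca <- bt$anc[[from]]; cb <- bt$anc[[to]]
  pos <- match(ca, cb)
  lca <- ca[which(!is.na(pos))[1]]
  upa <- ca[seq_len(match(lca, ca))]          # from .. lca
  upb <- cb[seq_len(match(lca, cb))]          # to .. lca
  units <- c(upa, rev(upb[-length(upb)]))
  n <- length(units)
  entry <- rep(NA_character_, n); exit <- rep(NA_character_, n)
  # climbing from -> lca: unit k exits at its parent-edge 'my' ref,
  # unit k+1 is entered at the parent-edge 'other' ref
  if (length(upa) > 1L) for (k in seq_len(length(upa) - 1L)) {
    pe <- bt$pedge[[upa[k]]]
    exit[k] <- pe$my
    entry[k + 1L] <- pe$other
  }
  # descending lca -> to
  if (length(upb) > 1L) {
    down <- rev(upb)   # lca .. to
    off <- length(upa) - 1L
    for (k in seq_len(length(down) - 1L)) {
      pe <- bt$pedge[[down[k + 1L]]]
      exit[off + k] <- pe$other
      entry[off + k + 1L] <- pe$my
    }
  }
  list(units = units, entry = entry, exit = exit)
}

# ---- per-unit factor access (with recursion into structure types) -----------

strip_label <- function(local) sub("#.*$", "", local)

unit_beta_lang <- function(w, u, generic = FALSE) {
  if (u$kind == "su") {
    bf <- subunit_type(u$type)$beta_fixed
    if (!is.null(bf)) return(bf)
    return(sym(paste0("beta_", u$tag)))
  }
  cache_get(w, paste0("beta|", u$type), {
    sc <- scope_of_type(w, u$type)
    fold_lang(mk_nary("SUM", lapply(sc$units, unit_beta_lang, w = w)))
  })
}

unit_F_lang <- function(w, u, generic = FALSE) {
  if (u$kind == "su") {
    if (generic) {
      if (!is.null(subunit_type(u$type)$beta_fixed)) return(NULL)
      return(sym(paste0("F_", u$tag)))
    }
    type <- subunit_type(u$type)
    if (identical(type$beta_fixed, 0)) return(NULL)
    return(subunit_factor(u$type, "F", tag = u$tag)$expr)
  }
  cache_get(w, paste0("F|", u$type),
            assemble_form_factor(w, scope_of_type(w, u$type),
                                 normalized = TRUE)$expr)
}

unit_A_lang <- function(w, u, local, generic = FALSE) {
  if (u$kind == "su") {
    ref <- strip_label(local)
    if (generic) return(sym(paste0("A_", u$tag, "_", ref)))
    return(cache_get(w, paste0("suA|", u$type, "|", u$tag, "|", ref),
                     subunit_factor(u$type, "A", ref, tag = u$tag)$expr))
  }
  cache_get(w, paste0("A|", u$type, "|", local), {
    sc <- scope_of_type(w, u$type)
    sl <- split_local(local)
    assemble_amplitude(w, sc, sl$member, sl$rest, normalized = TRUE)$expr
  })
}

unit_Psi_lang <- function(w, u, local_in, local_out, generic = FALSE) {
  if (identical(local_in, local_out)) return(1)  # same realized point
  if (u$kind == "su") {
    r1 <- strip_label(local_in); r2 <- strip_label(local_out)
    if (generic) {
      rr <- sort(c(r1, r2))
      return(sym(paste0("Psi_", u$tag, "_", rr[1], "_", rr[2])))
    }
    return(cache_get(w, paste0("suPsi|", u$type, "|", u$tag, "|", r1, "|", r2),
                     subunit_factor(u$type, "Psi", c(r1, r2),
                                    tag = u$tag)$expr))
  }
  k <- paste(sort(c(local_in, local_out)), collapse = "||")
  cache_get(w, paste0("Psi|", u$type, "|", k), {
    sc <- scope_of_type(w, u$type)
    s1 <- split_local(local_in); s2 <- split_local(local_out)
    assemble_phase(w, sc, s1$member, s1$rest, s2$member, s2$rest)$expr
  })
}

cache_get <- function(w, key, value) {
  if (!is.null(w$cache[[key]])) return(w$cache[[key]])
  v <- value
  w$cache[[key]] <- v
  v
}

local_of_key <- function(key) sub("^[^|]+\\|", "", key)

# ---- assembly ---------------------------------------------------------------

beta_sum_lang <- function(w, scope) {
  fold_lang(mk_nary("SUM", lapply(scope$units, unit_beta_lang, w = w)))
}

path_factors <- function(w, scope, bt, I, J, generic = FALSE) {
  # amplitude-psi-...-amplitude factor list for the ordered pair (I, J)
  p <- tree_path(bt, I, J)
  n <- length(p$units)
  fac <- list()
  uI <- scope$units[[I]]; uJ <- scope$units[[J]]
  fac[[1]] <- unit_A_lang(w, uI, local_of_key(p$exit[1]), generic)
  if (n > 2L) for (k in 2:(n - 1L)) {
    u <- scope$units[[p$units[k]]]
    psi <- unit_Psi_lang(w, u, local_of_key(p$entry[k]),
                         local_of_key(p$exit[k]), generic)
    if (!num1(psi) || psi != 1) fac[[length(fac) + 1L]] <- psi
  }
  fac[[length(fac) + 1L]] <- unit_A_lang(w, uJ, local_of_key(p$entry[n]),
                                         generic)
  fac
}

assemble_form_factor <- function(w, scope, normalized = TRUE,
                                 generic = FALSE) {
  units <- scope$units
  n <- length(units)
  betas <- lapply(units, unit_beta_lang, w = w)
  visible <- !vapply(betas, function(b) num1(b) && b == 0, logical(1))
  terms <- list()
  info <- list()
  for (nm in names(units)) {
    if (!visible[[nm]]) next
    Fi <- unit_F_lang(w, units[[nm]], generic)
    if (is.null(Fi)) next
    terms[[length(terms) + 1L]] <-
      mk_nary("PROD", list(mk_pow(betas[[nm]], 2), Fi))
    info[[length(info) + 1L]] <- list(kind = "form", I = nm, J = nm, mult = 1L)
  }
  nms <- names(units)[visible[names(units)]]
  if (length(nms) > 1L) {
    adj <- scope_adjacency(scope)
    bt <- bfs_tree(adj, names(units)[1])
    if (length(bt$order) != n)
      stop("structure is not connected")
    for (i in seq_along(nms)[-length(nms)]) for (j in (i + 1):length(nms)) {
      I <- nms[i]; J <- nms[j]
      fac <- path_factors(w, scope, bt, I, J, generic)
      terms[[length(terms) + 1L]] <-
        mk_nary("PROD", c(list(2, betas[[I]], betas[[J]]), fac))
      info[[length(info) + 1L]] <- list(kind = "pair", I = I, J = J, mult = 2L)
    }
  }
  expr <- mk_nary("SUM", terms)
  bsum <- beta_sum_lang(w, scope)
  if (normalized) {
    if (num1(bsum) && bsum == 0)
      stop("cannot normalize: total excess scattering length is zero")
    expr <- mk_div(expr, mk_pow(bsum, 2))
  }
  out <- sk_expr(expr, free_params(expr))
  attr(out, "n_units") <- n
  attr(out, "n_form_terms") <- sum(vapply(info, function(x) x$kind == "form",
                                          logical(1)))
  attr(out, "n_interference_terms") <-
    sum(vapply(info, function(x) if (x$kind == "pair") x$mult else 0L,
               integer(1)))
  attr(out, "terms") <- info
  out
}

assemble_amplitude <- function(w, scope, unit0, local0, normalized = TRUE) {
  units <- scope$units
  u0 <- units[[unit0]]
  betas <- lapply(units, unit_beta_lang, w = w)
  adj <- scope_adjacency(scope)
  bt <- bfs_tree(adj, unit0)
  if (length(bt$order) != length(units)) stop("structure is not connected")
  terms <- list()
  for (nm in names(units)) {
    b <- betas[[nm]]
    if (num1(b) && b == 0) next
    if (nm == unit0) {
      terms[[length(terms) + 1L]] <-
        mk_nary("PROD", list(b, unit_A_lang(w, u0, local0)))
      next
    }
    p <- tree_path(bt, unit0, nm)
    n <- length(p$units)
    fac <- list()
    psi0 <- unit_Psi_lang(w, u0, local0, local_of_key(p$exit[1]))
    if (!num1(psi0) || psi0 != 1) fac[[length(fac) + 1L]] <- psi0
    if (n > 2L) for (k in 2:(n - 1L)) {
      u <- units[[p$units[k]]]
      psi <- unit_Psi_lang(w, u, local_of_key(p$entry[k]),
                           local_of_key(p$exit[k]))
      if (!num1(psi) || psi != 1) fac[[length(fac) + 1L]] <- psi
    }
    fac[[length(fac) + 1L]] <-
      unit_A_lang(w, units[[nm]], local_of_key(p$entry[n]))
    terms[[length(terms) + 1L]] <- mk_nary("PROD", c(list(b), fac))
  }
  expr <- mk_nary("SUM", terms)
  if (normalized) {
    bsum <- beta_sum_lang(w, scope)
    if (num1(bsum) && bsum == 0)
      stop("cannot normalize: total excess scattering length is zero")
    expr <- mk_div(expr, bsum)
  }
  sk_expr(expr, free_params(expr))
}

assemble_phase <- function(w, scope, unit1, local1, unit2, local2) {
  units <- scope$units
  if (unit1 == unit2) {
    e <- unit_Psi_lang(w, units[[unit1]], local1, local2)
    return(sk_expr(e, free_params(e)))
  }
  adj <- scope_adjacency(scope)
  bt <- bfs_tree(adj, unit1)
  if (!unit2 %in% bt$order)
    stop("reference points lie in disconnected structures")
  p <- tree_path(bt, unit1, unit2)
  n <- length(p$units)
  fac <- list()
  add <- function(psi) if (!num1(psi) || psi != 1)
    fac[[length(fac) + 1L]] <<- psi
  add(unit_Psi_lang(w, units[[unit1]], local1, local_of_key(p$exit[1])))
  if (n > 2L) for (k in 2:(n - 1L))
    add(unit_Psi_lang(w, units[[p$units[k]]], local_of_key(p$entry[k]),
                      local_of_key(p$exit[k])))
  add(unit_Psi_lang(w, units[[unit2]], local_of_key(p$entry[n]), local2))
  e <- mk_nary("PROD", fac)
  sk_expr(e, free_params(e))
}

# ---- public API -------------------------------------------------------------

structure_scope <- function(w, name) {
  if (is.numeric(name)) return(scope_of_graph(w, name))
  if (name %in% names(w$stypes)) return(scope_of_type(w, name))
  u <- w$units[[name]]
  if (!is.null(u)) return(scope_of_graph(w, u$graph))
  stop("unknown structure, unit or graph: '", name, "'")
}

#' Composite form factor of a structure
#'
#' Assembles the normalized form factor F(q) of a wrapped structure type, a
#' live graph (named by any of its units or by graph id), enumerating one
#' form-factor term per sub-unit and one interference term per ordered pair
#' of sub-units along the unique connecting path.
#'
#' @param w an `sk_world`.
#' @param structure_name a structure type name, unit name, or graph id.
#' @param normalized divide by the squared total excess scattering length
#'   so that F(0) = 1 (default TRUE).
#' @param generic return the generic structural equation with abstract
#'   `F_i`, `A_i_ref`, `Psi_i_ref_ref` symbols instead of the sub-unit
#'   closed forms.
#' @return an `sk_expr`; attributes `n_units`, `n_form_terms` and
#'   `n_interference_terms` record the term bookkeeping.
#' @export
form_factor <- function(w, structure_name, normalized = TRUE,
                        generic = FALSE) {
  stopifnot(inherits(w, "sk_world"))
  assemble_form_factor(w, structure_scope(w, structure_name),
                       normalized = normalized, generic = generic)
}

#' Composite form factor amplitude relative to a reference point
#'
#' @param w an `sk_world`.
#' @param ref address of the reference point, e.g. `"DiBlock:A.end1"`.
#' @param normalized divide by the total excess scattering length (default
#'   TRUE, so the amplitude tends to 1 at q = 0).
#' @return an `sk_expr`.
#' @export
form_factor_amplitude <- function(w, ref, normalized = TRUE) {
  stopifnot(inherits(w, "sk_world"))
  r <- resolve_ref(w, ref)
  assemble_amplitude(w, r$scope, r$unit, r$local, normalized = normalized)
}

#' Composite phase factor between two reference points
#'
#' The product of sub-unit phase factors along the unique path connecting
#' the two realized reference points; contains no contrast parameters.
#'
#' @param w an `sk_world`.
#' @param ref1,ref2 reference addresses in the same structure.
#' @return an `sk_expr`.
#' @export
phase_factor <- function(w, ref1, ref2) {
  stopifnot(inherits(w, "sk_world"))
  r1 <- resolve_ref(w, ref1)
  r2 <- resolve_ref(w, ref2)
  if (!identical(r1$root, r2$root))
    stop("reference points lie in different structures ('", ref1, "' vs '",
         ref2, "')")
  assemble_phase(w, r1$scope, r1$unit, r1$local, r2$unit, r2$local)
}

#' Interference term of one ordered pair of units
#'
#' The contribution beta_I beta_J A_I (prod Psi) A_J of the ordered pair
#' (I, J) to the unnormalized composite form factor.
#'
#' @param w an `sk_world`.
#' @param I,J names of two distinct units in the same live graph.
#' @return an `sk_expr`.
#' @export
pair_term <- function(w, I, J) {
  stopifnot(inherits(w, "sk_world"))
  if (identical(I, J))
    stop("I and J must differ: the diagonal contribution is the form ",
         "factor term beta^2 F, not a pair term")
  uI <- w$units[[I]]; uJ <- w$units[[J]]
  if (is.null(uI)) stop("unknown unit: '", I, "'")
  if (is.null(uJ)) stop("unknown unit: '", J, "'")
  if (uI$graph != uJ$graph)
    stop("units '", I, "' and '", J, "' are not connected")
  scope <- scope_of_graph(w, uI$graph)
  adj <- scope_adjacency(scope)
  bt <- bfs_tree(adj, I)
  fac <- path_factors(w, scope, bt, I, J)
  e <- mk_nary("PROD", c(list(unit_beta_lang(w, uI), unit_beta_lang(w, uJ)),
                         fac))
  sk_expr(e, free_params(e))
}

# PascalCase aliases matching the builder-method names these operations are
# known by in scattering software.

#' @rdname form_factor
#' @export
FormFactor <- form_factor

#' @rdname form_factor_amplitude
#' @export
FormFactorAmplitude <- form_factor_amplitude

#' @rdname phase_factor
#' @export
PhaseFactor <- phase_factor

#' Generic composite form factor (abstract sub-unit symbols)
#' @inheritParams form_factor
#' @export
FormFactorGeneric <- function(w, structure_name)
  form_factor(w, structure_name, normalized = FALSE, generic = TRUE)
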