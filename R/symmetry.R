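# Symmetry group of a rivalry network: all node permutations preserving cell
# classes, the typed inhibitory arrow set, and the typed excitatory arrow
# multiset (directed arrows with their classes and multiplicities).

# n x n character relation matrix: entry [i, j] encodes every arrow from i to
# j (class and multiplicity); diagonal carries the cell class. A permutation
# p is an automorphism iff M[p, p] == M elementwise.
.relation_matrix <- function(network) {
  n <- network$n_nodes
  M <- matrix("", n, n)
  diag(M) <- paste0("cell:", network$nodes$cell_class[order(network$nodes$node)])
  add <- function(i, j, lab) M[i, j] <<- paste0(M[i, j], ";", lab)
  inh <- network$inhibitory
  for (r in seq_len(nrow(inh))) {
    lab <- inh$class[r]
    add(inh$from[r], inh$to[r], lab)
    add(inh$to[r], inh$from[r], lab)
  }
  exc <- network$excitatory
  for (r in seq_len(nrow(exc))) {
    lab <- paste0(exc$class[r], "#", exc$multiplicity[r])
    add(exc$from[r], exc$to[r], lab)
    if (!exc$directed[r]) add(exc$to[r], exc$from[r], lab)
  }
  M
}

.is_automorphism <- function(p, M) identical(M[p, p], M)

# depth-first search with pruning on partial arrow preservation
.automorphisms_backtrack <- function(M) {
  n <- nrow(M)
  # candidate images share the node signature: diagonal label plus the sorted
  # multiset of incident relation labels
  sig <- vapply(seq_len(n), function(i) {
    paste(M[i, i], paste(sort(M[i, -i]), collapse = "|"),
          paste(sort(M[-i, i]), collapse = "|"), sep = "$")
  }, character(1))
  cand <- lapply(seq_len(n), function(i) which(sig == sig[i]))
  # assign most-constrained nodes first
  ord <- order(lengths(cand))
  found <- list()
  img <- integer(n)
  used <- logical(n)
  recurse <- function(k) {
    if (k > n) { found[[length(found) + 1L]] <<- img; return(invisible()) }
    i <- ord[k]
    prev <- ord[seq_len(k - 1L)]
    for (c in cand[[i]]) {
      if (used[c]) next
      ok <- TRUE
      for (j in prev) {
        if (M[c, img[j]] != M[i, j] || M[img[j], c] != M[j, i]) { ok <- FALSE; break }
      }
      if (!ok) next
      img[i] <<- c; used[c] <<- TRUE
      recurse(k + 1L)
      used[c] <<- FALSE
    }
  }
  recurse(1L)
  found
}

#' Automorphism group of a rivalry network
#'
#' Computes all node permutations that preserve cell classes, the inhibitory
#' arrow set with its classes, and the excitatory arrow multiset with classes
#' and multiplicities. The result is verified to be closed under composition.
#'
#' @param network A [rivalry_network()].
#' @param method `"backtrack"` (pruned search, default) or `"naive"`
#'   (enumeration of all n! permutations; oracle for small networks).
#' @param max_nodes Size guard for the search (default 16).
#' @return An object of class `symmetry_group` with `elements` (list of
#'   integer permutation vectors), `order`, `generators`, `n`.
#' @examples
#' automorphism_group(paper_network("scrambled-monkey-text"))
#' @export
automorphism_group <- function(network, method = c("backtrack", "naive"),
                               max_nodes = 16L) {
  stopifnot(inherits(network, "rivalry_network"))
  method <- match.arg(method)
  n <- network$n_nodes
  if (n > max_nodes) {
    abort(paste0("network has ", n, " nodes, above the search bound of ",
                 max_nodes, " (raise max_nodes if intended)"))
  }
  M <- .relation_matrix(network)
  elems <- if (method == "naive") {
    if (n > 9L) abort("naive enumeration supported only for n <= 9")
    keep(all_permutations(n), .is_automorphism, M = M)
  } else {
    .automorphisms_backtrack(M)
  }
  grp <- new_symmetry_group(elems, n)
  if (!.group_closed(grp)) abort("internal error: automorphism set not closed")
  grp
}

new_symmetry_group <- function(elems, n) {
  keys <- map_chr(elems, perm_key)
  o <- order(keys)
  elems <- elems[o]
  structure(
    list(elements = elems, order = length(elems), n = n,
         keys = keys[o], generators = .minimal_generators(elems, n)),
    class = "symmetry_group"
  )
}

.group_closed <- function(group) {
  keys <- group$keys
  id <- perm_key(seq_len(group$n))
  if (!id %in% keys) return(FALSE)
  for (a in group$elements) {
    if (!perm_key(perm_inverse(a)) %in% keys) return(FALSE)
    for (b in group$elements) {
      if (!perm_key(perm_compose(a, b)) %in% keys) return(FALSE)
    }
  }
  TRUE
}

# greedy small generating set, preferring elements that move few points so
# the printed generators look like the published transposition products
.minimal_generators <- function(elems, n) {
  idk <- perm_key(seq_len(n))
  nontriv <- keep(elems, \(p) perm_key(p) != idk)
  if (length(nontriv) == 0L) return(list())
  moved <- map_int(nontriv, \(p) sum(p != seq_len(n)))
  nontriv <- nontriv[order(moved, map_chr(nontriv, perm_key))]
  gens <- list()
  have <- idk
  for (p in nontriv) {
    if (perm_key(p) %in% have) next
    gens <- c(gens, list(p))
    have <- map_chr(perm_closure(gens, n), perm_key)
    if (length(have) == length(elems)) break
  }
  gens
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat("<symmetry_group> order ", x$order, " on ", x$n, " nodes\n", sep = "")
  cat("  generators: ",
      paste(map_chr(x$generators, perm_cycles), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.symmetry_group <- function(x, ...) {
  tibble(
    element = map_chr(x$elements, perm_cycles),
    order = map_int(x$elements, perm_order),
    moved = map_int(x$elements, \(p) sum(p != seq_len(x$n)))
  )
}

#' @export
glance.symmetry_group <- function(x, ...) {
  tibble(order = x$order, n_nodes = x$n,
         n_generators = length(x$generators),
         name = group_name(x))
}

#' Test whether a permutation belongs to a symmetry group
#' @param group A `symmetry_group`.
#' @param p Integer permutation vector.
#' @return Logical.
#' @export
group_contains <- function(group, p) perm_key(p) %in% group$keys

#' Level-swap elements of a symmetry group
#'
#' Elements mapping at least one node to a different node of the same
#' attribute column. The canonical eye swap (the element mapping every column
#' to itself and acting nontrivially in every column that any level swap
#' moves internally) is attached as attribute `canonical_rho` when present.
#'
#' @param group A `symmetry_group` computed for `network`.
#' @param network The [rivalry_network()] the group belongs to.
#' @return List of permutations (possibly empty) with attribute
#'   `canonical_rho` (a permutation or `NULL`).
#' @export
level_swap_elements <- function(group, network) {
  colv <- network$nodes$column[order(network$nodes$node)]
  is_swap <- map_lgl(group$elements, \(p) any(p != seq_len(group$n) & colv[p] == colv))
  swaps <- group$elements[is_swap]
  movable <- unique(unlist(map(swaps, \(p) {
    colv[p != seq_len(group$n) & colv[p] == colv]
  })))
  fixes_cols <- function(p) all(colv[p] == colv)
  moves_all_movable <- function(p) {
    moved_cols <- unique(colv[p != seq_len(group$n)])
    all(movable %in% moved_cols)
  }
  cands <- keep(swaps, \(p) fixes_cols(p) && moves_all_movable(p))
  rho <- NULL
  if (length(cands) > 0L) {
    # prefer involutions moving the fewest nodes, then lexicographic
    ordc <- order(map_int(cands, perm_order),
                  map_int(cands, \(p) sum(p != seq_len(group$n))),
                  map_chr(cands, perm_key))
    rho <- cands[[ordc[1]]]
  }
  attr(swaps, "canonical_rho") <- rho
  swaps
}

#' Canonical eye-swap element of a network's symmetry group
#' @inheritParams level_swap_elements
#' @return A permutation or `NULL` when the network has no such element.
#' @export
canonical_rho <- function(group, network) {
  attr(level_swap_elements(group, network), "canonical_rho")
}

#' Fixed-point subspace of a set of symmetries
#'
#' The fixed-point subspace of the subgroup generated by `elements`,
#' expressed as node-equality (synchrony) classes: states constant on each
#' orbit of the generated subgroup. For the full symmetry group these are the
#' maximal fusion states.
#'
#' @param elements List of permutations (may be empty).
#' @param n_nodes Number of nodes.
#' @return An object of class `fusion_subspace` with `classes` (list of node
#'   id vectors), `basis` (n-by-d orthonormal indicator basis), `dimension`.
#' @export
fixed_point_subspace <- function(elements, n_nodes) {
  closure <- perm_closure(elements, n_nodes)
  # orbits of the generated subgroup
  rep_of <- seq_len(n_nodes)
  for (p in closure) {
    for (i in seq_len(n_nodes)) {
      a <- min(rep_of[i], rep_of[p[i]])
      rep_of[rep_of == rep_of[i] | rep_of == rep_of[p[i]]] <- a
    }
  }
  classes <- split(seq_len(n_nodes), rep_of)
  names(classes) <- NULL
  classes <- classes[order(map_int(classes, min))]
  basis <- vapply(classes, function(cl) {
    v <- numeric(n_nodes)
    v[cl] <- 1 / sqrt(length(cl))
    v
  }, numeric(n_nodes))
  structure(
    list(classes = classes, basis = basis, dimension = length(classes)),
    class = "fusion_subspace"
  )
}

#' @export
print.fusion_subspace <- function(x, ...) {
  cat("<fusion_subspace> dimension ", x$dimension, " (per node dimension)\n",
      sep = "")
  cat("  synchrony classes: ",
      paste(map_chr(x$classes, \(cl) paste0("{", paste(cl, collapse = " "), "}")),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Node orbits of a symmetry group
#' @param group A `symmetry_group`.
#' @return List of integer vectors (orbits, sorted by smallest member).
#' @export
node_orbits <- function(group) {
  fixed_point_subspace(group$elements, group$n)$classes
}

# abstract fingerprint name for a small group given as element list
.name_abstract <- function(elems, n) {
  o <- length(elems)
  if (o == 1L) return("1")
  ords <- map_int(elems, perm_order)
  abelian <- all(map_lgl(elems, \(a) all(map_lgl(elems, \(b)
    identical(perm_compose(a, b), perm_compose(b, a))))))
  is_dihedral <- function(m) {
    # has r of order m and involution s outside <r> with (rs)^2 = id
    rs <- keep(elems, \(p) perm_order(p) == m)
    for (r in rs) {
      pow <- map_chr(perm_closure(list(r), n), perm_key)
      ss <- keep(elems, \(p) perm_order(p) == 2L && !perm_key(p) %in% pow)
      for (s in ss) {
        if (perm_order(perm_compose(r, s)) == 2L) return(TRUE)
      }
    }
    FALSE
  }
  if (o == 2L) return("Z2")
  if (o == 3L) return("Z3")
  if (o == 4L) return(if (max(ords) == 4L) "Z4" else "Z2 x Z2")
  if (o == 6L) return(if (abelian) "Z6" else "D3")
  if (o == 8L) {
    if (!abelian && is_dihedral(4L)) return("D4")
    if (abelian && max(ords) == 2L) return("Z2 x Z2 x Z2")
    return(paste0("order ", o))
  }
  if (o == 12L && !abelian && is_dihedral(6L)) return("D6")
  paste0("order ", o)
}

#' Named-group label for a symmetry group
#'
#' Identifies the small groups arising here (Z2, D2, D3, D4 and their direct
#' products with the eye swap) by order and generator relations; used for
#' report labels only.
#'
#' @param group A `symmetry_group`.
#' @param network Optionally the network, to factor out the canonical eye
#'   swap and label the group `"<H> x Z2(rho)"`.
#' @return A string.
#' @export
group_name <- function(group, network = NULL) {
  elems <- group$elements
  n <- group$n
  if (!is.null(network)) {
    rho <- canonical_rho(group, network)
    central <- function(p) all(map_lgl(elems, \(b)
      identical(perm_compose(p, b), perm_compose(b, p))))
    if (!is.null(rho) && central(rho)) {
      rk <- perm_key(rho)
      # coset multiplication on G/<rho>
      pairk <- map_chr(elems, \(p) min(perm_key(p), perm_key(perm_compose(rho, p))))
      reps <- elems[!duplicated(pairk)]
      # represent the quotient faithfully as permutations of its own cosets
      ckeys <- unique(pairk)
      qperm <- map(reps, function(g) {
        map_int(reps, function(h) {
          gh <- perm_compose(g, h)
          match(min(perm_key(gh), perm_key(perm_compose(rho, gh))), ckeys)
        })
      })
      return(paste0(.name_abstract(qperm, length(ckeys)),
                    " x Z2(", perm_cycles(rho), ")"))
    }
  }
  .name_abstract(elems, n)
}

#' Subgroup of a symmetry group generated by given elements
#' @param group A `symmetry_group`.
#' @param elements List of permutations belonging to `group`.
#' @return A `symmetry_group` (the generated subgroup).
#' @export
subgroup <- function(group, elements) {
  for (p in elements) {
    if (!group_contains(group, p)) abort("element not in group")
  }
  new_symmetry_group(perm_closure(elements, group$n), group$n)
}
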