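# Isotypic decomposition of the node-permutation representation of the
# network symmetry group, over the reals. Method: average gamma-conjugates of
# a random symmetric matrix to obtain a generic equivariant symmetric
# operator; its eigenspaces are single irreducible copies, which are merged
# into isotypic components when their characters agree. All groups arising
# here have only real-type irreducibles; anything else raises an error.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Isotypic decomposition of the permutation representation
#'
#' Decomposes the n-dimensional node-permutation representation of a network
#' symmetry group into its isotypic components (sums of all irreducible
#' subspaces of one isomorphism type). Dimensions are per node dimension k;
#' the internal dimension is only instantiated by the rate-equation model.
#'
#' @param group A `symmetry_group`.
#' @param seed Seed for the random symmetric draw (default 0); the resulting
#'   decomposition is deterministic and verified independent of the draw.
#' @param tol Numerical tolerance for invariance/idempotence verification.
#' @return Object of class `isotypic_decomposition`: a list of components,
#'   each with orthonormal `basis`, `dimension`, `irrep_dim`, `multiplicity`,
#'   `sign` map, `kernel`, and a human-readable integer `rendering`.
#' @examples
#' g <- automorphism_group(paper_network("scrambled-monkey-text"))
#' isotypic_decomposition(g)
#' @export
isotypic_decomposition <- function(group, seed = 0L, tol = 1e-8) {
  n <- group$n
  Ps <- map(group$elements, perm_matrix)
  S0 <- .with_seed(seed, matrix(rnorm(n * n), n, n))
  S <- S0 + t(S0)
  A <- Reduce(`+`, map(Ps, \(P) P %*% S %*% t(P))) / length(Ps)
  eg <- eigen(A, symmetric = TRUE)
  # cluster eigenvalues: each cluster spans one irreducible copy
  vals <- eg$values
  cl_id <- cumsum(c(TRUE, abs(diff(vals)) > 1e-6 * max(1, max(abs(vals)))))
  copies <- map(unique(cl_id), function(id) {
    Q <- eg$vectors[, cl_id == id, drop = FALSE]
    chars <- map_dbl(Ps, \(P) sum(diag(crossprod(Q, P %*% Q))))
    list(Q = Q, chars = chars, dim = ncol(Q))
  })
  # Frobenius-Schur indicator on each copy's character: must be ~1 (real type)
  sq_idx <- map_int(group$elements, \(p) match(perm_key(perm_compose(p, p)), group$keys))
  for (cp in copies) {
    fs <- mean(cp$chars[sq_idx])
    if (abs(fs - 1) > 1e-2) {
      abort("non-real irreducible representation type detected; outside scope")
    }
  }
  # merge copies with equal characters into isotypic components
  ckey <- map_chr(copies, \(cp) paste(round(cp$chars, 4), collapse = ","))
  comp_raw <- map(unique(ckey), function(k) {
    grp_copies <- copies[ckey == k]
    dims <- map_int(grp_copies, "dim")
    if (length(unique(dims)) != 1L) {
      abort("numerical-rank failure: copies of one type with unequal dimensions")
    }
    basis <- do.call(cbind, map(grp_copies, "Q"))
    list(basis = basis, irrep_dim = dims[1], multiplicity = length(grp_copies),
         chars = grp_copies[[1]]$chars)
  })
  comps <- map(comp_raw, \(cr) .finish_component(cr, group, Ps, tol))
  # verification: completeness and pairwise orthogonality
  if (sum(map_int(comps, \(cp) cp$dimension)) != n) {
    abort("numerical-rank failure: component dimensions do not sum to n")
  }
  allB <- do.call(cbind, map(comps, "basis"))
  if (max(abs(crossprod(allB) - diag(n))) > tol) {
    abort("numerical-rank failure: components not orthonormal")
  }
  # deterministic ordering: dimension, then lexicographic canonical basis
  ordk <- map_chr(comps, \(cp) paste(sprintf("%02d", cp$dimension),
                                     cp$rendering))
  comps <- comps[order(ordk)]
  for (i in seq_along(comps)) comps[[i]]$id <- i
  structure(list(components = comps, group = group, n = n),
            class = "isotypic_decomposition")
}

.finish_component <- function(cr, group, Ps, tol) {
  basis <- cr$basis
  n <- group$n
  # canonical basis: orbit projections for 1-D types, projector RREF otherwise
  proj <- tcrossprod(basis)
  canon <- if (cr$irrep_dim == 1L) {
    orbs <- node_orbits(group)
    vs <- map(orbs, \(o) proj %*% replace(numeric(n), min(o), 1))
    vs <- keep(vs, \(v) sqrt(sum(v^2)) > 1e-8)
    do.call(cbind, map(vs, \(v) v / sqrt(sum(v^2))))
  } else {
    .rref_basis(proj, ncol(basis))
  }
  if (is.null(canon) || ncol(canon) != ncol(basis)) canon <- basis
  # verify invariance of the span under every group element
  for (P in Ps) {
    act <- crossprod(canon, P %*% canon)
    resid <- max(abs(P %*% canon - canon %*% act))
    if (resid > 1e-7) abort("numerical-rank failure: component span not invariant")
  }
  sign_map <- map_int(Ps, function(P) {
    act <- crossprod(canon, P %*% canon)
    d <- ncol(canon)
    if (max(abs(act - diag(d))) < 1e-6) 1L
    else if (max(abs(act + diag(d))) < 1e-6) -1L
    else 0L
  })
  kernel <- group$elements[sign_map == 1L]
  rend <- .render_basis(canon)
  list(basis = canon, dimension = ncol(canon), irrep_dim = cr$irrep_dim,
       multiplicity = cr$multiplicity, chars = cr$chars, sign = sign_map,
       kernel = kernel, rendering = rend, projector = proj)
}

# orthonormal basis with canonical (reduced-row-echelon-like) structure,
# extracted from a projector with rational entries
.rref_basis <- function(proj, rank) {
  n <- nrow(proj)
  R <- proj
  piv <- integer(0)
  r <- 1L
  for (j in seq_len(n)) {
    if (r > rank) break
    i <- which.max(abs(R[r:n, j])) + r - 1L
    if (abs(R[i, j]) < 1e-8) next
    R[c(r, i), ] <- R[c(i, r), ]
    R[r, ] <- R[r, ] / R[r, j]
    for (k in seq_len(n)[-r]) R[k, ] <- R[k, ] - R[k, j] * R[r, ]
    piv <- c(piv, j)
    r <- r + 1L
  }
  B <- t(R[seq_along(piv), , drop = FALSE])
  # orthonormalize while keeping the echelon structure (Gram-Schmidt)
  for (j in seq_len(ncol(B))) {
    if (j > 1L) {
      for (k in seq_len(j - 1L)) {
        B[, j] <- B[, j] - sum(B[, j] * B[, k]) * B[, k]
      }
    }
    B[, j] <- B[, j] / sqrt(sum(B[, j]^2))
  }
  B
}

# continued-fraction rationalization of a vector to smallest integers
.rationalize <- function(v, tol = 1e-6, max_den = 64L) {
  nz <- which(abs(v) > 1e-7)
  if (length(nz) == 0L) return(rep(0L, length(v)))
  r <- v / v[nz[1]]
  frac <- function(x) {
    # best rational approximation with denominator <= max_den
    p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; x0 <- x
    repeat {
      a <- floor(x0)
      p2 <- a * p1 + p0; q2 <- a * q1 + q0
      if (q2 > max_den) break
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
      if (abs(x0 - a) < 1e-12) break
      x0 <- 1 / (x0 - a)
    }
    c(p1, q1)
  }
  pq <- t(vapply(r, frac, numeric(2)))
  dens <- pq[, 2]
  L <- Reduce(\(a, b) a * b / .gcd(a, b), unique(dens))
  ints <- round(r * L)
  if (max(abs(r * L - ints)) > tol * max(1, max(abs(ints)))) return(NULL)
  g <- Reduce(.gcd, abs(ints[ints != 0]))
  ints <- as.integer(ints / g)
  if (ints[which(ints != 0)[1]] < 0) ints <- -ints
  ints
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# human-readable rendering: per-node linear combination of symbols x, y, z, u
.render_basis <- function(B) {
  syms <- c("x", "y", "z", "u", "v", "w")
  m <- ncol(B)
  ints <- map(seq_len(m), \(j) .rationalize(B[, j]))
  if (any(map_lgl(ints, is.null)) || m > length(syms)) {
    return(paste0("<", nrow(B), "x", m, " numeric basis>"))
  }
  C <- do.call(cbind, ints)
  node_str <- vapply(seq_len(nrow(B)), function(i) {
    terms <- character(0)
    for (j in seq_len(m)) {
      c_ <- C[i, j]
      if (c_ == 0) next
      coef <- if (abs(c_) == 1) "" else as.character(abs(c_))
      op <- if (c_ > 0) "+" else "-"
      terms <- c(terms, paste0(op, coef, syms[j]))
    }
    if (length(terms) == 0L) return("0")
    s <- paste(terms, collapse = "")
    sub("^\\+", "", s)
  }, character(1))
  paste0("(", paste(node_str, collapse = ", "), ")")
}

#' Kernel of a group's action on an isotypic component
#'
#' The set of group elements acting as the identity on the component,
#' returned as a subgroup with a recognizable name when possible.
#'
#' @param component A component from [isotypic_decomposition()].
#' @param group The `symmetry_group` the decomposition was computed for.
#' @return A `symmetry_group` (the kernel subgroup) with attribute `label`.
#' @export
component_kernel <- function(component, group) {
  ker <- new_symmetry_group(component$kernel, group$n)
  attr(ker, "label") <- .kernel_label(ker, group)
  ker
}

.kernel_label <- function(ker, group) {
  if (ker$order == 1L) return("1")
  if (ker$order == group$order) return("full group")
  if (ker$order == 2L) {
    g <- keep(ker$elements, \(p) any(p != seq_len(ker$n)))[[1]]
    return(paste0("Z2(", perm_cycles(g), ")"))
  }
  nm <- .name_abstract(ker$elements, ker$n)
  if (nm == "Z2 x Z2") nm <- "D2"
  nm
}

#' Flag the fusion-breaking isotypic components
#'
#' A fusion-breaking Hopf bifurcation has its center subspace in an isotypic
#' component on which the canonical eye swap acts as minus the identity.
#' Components on which any level-swap element acts trivially are additionally
#' annotated as leading to (partial) fusion.
#'
#' @param decomposition An [isotypic_decomposition()].
#' @param level_swaps Result of [level_swap_elements()] for the same network
#'   and group (carries the canonical eye swap).
#' @return The decomposition with components annotated
#'   (`fusion_breaking`, `leads_to_fusion`, `unclassified`).
#' @export
fusion_breaking_components <- function(decomposition, level_swaps) {
  rho <- attr(level_swaps, "canonical_rho")
  if (is.null(rho)) {
    abort(paste0("no canonical eye-swap element found: the network is outside ",
                 "the binocular level-swap scheme"))
  }
  group <- decomposition$group
  rho_i <- match(perm_key(rho), group$keys)
  swap_i <- map_int(level_swaps, \(p) match(perm_key(p), group$keys))
  decomposition$components <- map(decomposition$components, function(cp) {
    s <- cp$sign[rho_i]
    cp$fusion_breaking <- s == -1L
    cp$unclassified <- s == 0L
    cp$leads_to_fusion <- any(cp$sign[swap_i] == 1L)
    cp
  })
  decomposition$rho <- rho
  decomposition
}

#' @export
print.isotypic_decomposition <- function(x, ...) {
  cat("<isotypic_decomposition> ", length(x$components),
      " components of the ", x$n, "-node permutation representation\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.isotypic_decomposition <- function(x, ...) {
  group <- x$group
  rho_i <- if (!is.null(x$rho)) match(perm_key(x$rho), group$keys) else NA_integer_
  tibble(
    component = map_int(x$components, "id"),
    dim_per_k = map_int(x$components, "dimension"),
    irrep_dim = map_int(x$components, "irrep_dim"),
    multiplicity = map_int(x$components, "multiplicity"),
    basis = map_chr(x$components, "rendering"),
    sign_rho = if (is.na(rho_i)) NA_integer_ else
      map_int(x$components, \(cp) cp$sign[rho_i]),
    kernel = map_chr(x$components, \(cp)
      .kernel_label(new_symmetry_group(cp$kernel, x$n), group)),
    fusion_breaking = map_lgl(x$components, \(cp)
      isTRUE(cp$fusion_breaking)),
    leads_to_fusion = map_lgl(x$components, \(cp)
      isTRUE(cp$leads_to_fusion))
  )
}

#' Decomposition table with eye-swap-trivial components merged
#'
#' Merges all components on which the canonical eye swap acts trivially into
#' a single fusion block (they can never carry a fusion-breaking bifurcation),
#' reproducing the compact presentation used for the four-dot networks.
#'
#' @param decomposition An annotated decomposition
#'   (see [fusion_breaking_components()]).
#' @return A tibble like [tidy.isotypic_decomposition()], with one merged
#'   `fusion block` row.
#' @export
decomposition_report <- function(decomposition) {
  if (is.null(decomposition$rho)) {
    abort("decomposition is not annotated; run fusion_breaking_components() first")
  }
  tb <- tidy(decomposition)
  triv <- !tb$fusion_breaking
  if (sum(triv) <= 1L) return(tb)
  merged <- tibble(
    component = NA_integer_,
    dim_per_k = sum(tb$dim_per_k[triv]),
    irrep_dim = NA_integer_, multiplicity = NA_integer_,
    basis = "fusion block (eye swap acts trivially)",
    sign_rho = 1L, kernel = NA_character_,
    fusion_breaking = FALSE, leads_to_fusion = TRUE
  )
  bind_rows(tb[!triv, ], merged)
}
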