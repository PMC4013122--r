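# Catalog of periodic solution branches predicted by equivariant Hopf theory
# for the representation types arising in rivalry networks: any 1-D type, and
# the 2-D standard representations of D3 and D4 (with the eye-swap factor).
# Anything else raises an explicit "outside catalog" error.

#' Waveform templates for rendering predicted periodic solutions
#'
#' Phase-shifted cosine family used to render branches: the k-th independent
#' wave label is `cos(2*pi*freq*(t + theta - (k-1)*delta))`, so distinct
#' waves are offset by `delta` (default 0.2); frequency-2 waves satisfy
#' `z_0 = z_{1/2}`. Constant (fused) labels evaluate to a fixed level.
#'
#' @param delta Phase offset between independent waves (fraction of period).
#' @return Object of class `waveform_template`.
#' @export
waveform_template <- function(delta = 0.2) {
  structure(list(delta = delta), class = "waveform_template")
}

# evaluate branch signals on a time grid; returns nodes x length(t) matrix
branch_signals <- function(branch, t, template = waveform_template(),
                           const_values = NULL) {
  pat <- branch$pattern
  osc <- unique(pat$wave[!pat$const])
  off <- setNames((seq_along(osc) - 1) * template$delta, osc)
  X <- matrix(0, nrow(pat), length(t))
  for (i in seq_len(nrow(pat))) {
    if (pat$const[i]) {
      v <- 0
      if (!is.null(const_values) && pat$wave[i] %in% names(const_values)) {
        v <- const_values[[pat$wave[i]]]
      }
      X[i, ] <- v
    } else {
      X[i, ] <- cos(2 * pi * pat$freq[i] * (t + pat$theta[i] - off[[pat$wave[i]]]))
    }
  }
  rownames(X) <- pat$node
  X[order(pat$node), , drop = FALSE]
}

.new_branch <- function(name, pattern, component_id = NA_integer_) {
  pattern <- pattern |> arrange(.data$node) |>
    mutate(theta = .data$theta %% 1)
  structure(list(name = name, pattern = pattern, component_id = component_id),
            class = "solution_branch")
}

#' @export
print.solution_branch <- function(x, ...) {
  lab <- x$pattern |>
    mutate(s = ifelse(.data$const, .data$wave,
                      paste0(.data$wave, "_", .theta_str(.data$theta),
                             ifelse(.data$freq == 2, "*", "")))) |>
    pull("s")
  cat("<solution_branch> ", x$name, "\n  (",
      paste(lab, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

.theta_str <- function(th) {
  fr <- vapply(th, function(x) {
    for (d in c(1L, 2L, 3L, 4L, 6L, 8L, 12L)) {
      nn <- x * d
      if (abs(nn - round(nn)) < 1e-9) return(paste0(round(nn), "/", d))
    }
    format(x)
  }, character(1))
  sub("^0/1$", "0", sub("/1$", "", fr))
}

#' @export
tidy.solution_branch <- function(x, ...) x$pattern

# canonical eye-swap rows: for each 2-level column the node pair swapped by
# rho; "row 1" is the node belonging to the first learned pattern
.rho_rows <- function(network, rho) {
  nodes <- network$nodes
  p1 <- sort(network$patterns$node[network$patterns$pattern ==
                                     min(network$patterns$pattern)])
  row1 <- intersect(seq_len(network$n_nodes), p1)
  list(row1 = row1, row2 = rho[row1])
}

#' Predicted periodic solution branches for a fusion-breaking component
#'
#' Maps a fusion-breaking isotypic component to its catalog of periodic
#' solution branches (spatial phase-shift patterns) given by equivariant Hopf
#' theory: a single branch for 1-D representation types (zero-entry nodes
#' become frequency-2 fused waves), and three branches each for the 2-D
#' standard representations of D3 (rotating wave, two-in-phase, fused-node
#' standing) and D4 (antiphase standing, fused-node standing, rotating wave).
#'
#' @param component A component of an annotated [isotypic_decomposition()].
#' @param group The network's `symmetry_group`.
#' @param network The [rivalry_network()].
#' @return List of `solution_branch` objects.
#' @export
predict_branches <- function(component, group, network) {
  if (!isTRUE(component$fusion_breaking)) {
    abort("component is not flagged fusion-breaking; no branch predictions")
  }
  if (component$irrep_dim == 1L) {
    list(.branch_1d(component, group, network))
  } else if (component$irrep_dim == 2L) {
    .branches_2d(component, group, network)
  } else {
    abort(paste0("representation type (irreducible dimension ",
                 component$irrep_dim, ") is outside the branch catalog"))
  }
}

# orbit-based constant labels c1, c2, ... for nodes not oscillating
.const_rows <- function(const_nodes, group) {
  if (length(const_nodes) == 0L) {
    return(tibble(node = integer(), wave = character(), theta = numeric(),
                  freq = numeric(), const = logical()))
  }
  orbs <- keep(node_orbits(group), \(o) any(o %in% const_nodes))
  bind_rows(imap(orbs, \(o, i) tibble(
    node = intersect(o, const_nodes), wave = paste0("c", i),
    theta = 0, freq = 2, const = TRUE
  )))
}

.branch_1d <- function(component, group, network) {
  B <- component$basis
  m <- ncol(B)
  waves <- if (m == 1L) "a" else c("x", "y", "z", "u", "v", "w")[seq_len(m)]
  rows <- list()
  for (j in seq_len(m)) {
    v <- B[, j]
    nz <- which(abs(v) > 1e-8)
    # orientation: first involved node at phase 0
    if (v[nz[1]] < 0) v <- -v
    rows[[j]] <- tibble(node = nz, wave = waves[j],
                        theta = ifelse(v[nz] > 0, 0, 0.5),
                        freq = 1, const = FALSE)
  }
  osc <- bind_rows(rows)
  const_nodes <- setdiff(seq_len(group$n), osc$node)
  pat <- bind_rows(osc, .const_rows(const_nodes, group))
  .new_branch("pure antiphase", pat, component$id)
}

.branches_2d <- function(component, group, network) {
  rho <- canonical_rho(group, network)
  if (is.null(rho)) abort("no canonical eye swap; 2-D catalog unavailable")
  rows <- .rho_rows(network, rho)
  n <- group$n
  B <- component$basis
  act <- function(p) crossprod(B, perm_matrix(p) %*% B)
  # rotation element: determinant +1 action, order 3 or 4, row-preserving
  cands <- keep(group$elements, function(p) {
    if (identical(p, seq_len(n))) return(FALSE)
    if (!all(p[rows$row1] %in% rows$row1)) return(FALSE)
    A <- act(p)
    abs(det(A) - 1) < 1e-6 && perm_order(p) %in% c(3L, 4L)
  })
  m <- NULL
  r <- NULL
  for (p in cands) {
    tr <- sum(diag(act(p)))
    if (abs(tr + 1) < 1e-6 && perm_order(p) == 3L) { m <- 3L; r <- p; break }
    if (abs(tr) < 1e-6 && perm_order(p) == 4L) { m <- 4L; r <- p; break }
  }
  if (is.null(m)) {
    abort("2-D component is not a standard D3/D4 representation: outside catalog")
  }
  base <- min(rows$row1)
  cyc <- integer(m)
  cyc[1] <- base
  for (k in 2:m) cyc[k] <- r[cyc[k - 1]]
  with_row2 <- function(pat1) {
    # extend a row-1 assignment by the eye swap: theta + 1/2 (frequency-2
    # waves are unchanged by the half-period shift)
    pat2 <- pat1 |>
      mutate(node = rho[.data$node],
             theta = ifelse(.data$freq == 2, .data$theta, .data$theta + 0.5))
    bind_rows(pat1, pat2)
  }
  reflections <- keep(group$elements, function(p) {
    if (!all(p[rows$row1] %in% rows$row1)) return(FALSE)
    perm_order(p) == 2L && abs(det(act(p)) + 1) < 1e-6
  })
  branches <- list()
  if (m == 3L) {
    # rotating wave: successive columns shifted by a third of a period
    rw <- tibble(node = cyc, wave = "x", theta = (seq_len(3) - 1) / 3,
                 freq = 1, const = FALSE)
    branches$rw <- .new_branch("rotating wave", with_row2(rw), component$id)
    s <- reflections[[1]]
    fixed <- cyc[s[cyc] == cyc]
    swapped <- setdiff(cyc, fixed)
    if (length(fixed) != 1L) abort("unexpected reflection structure")
    tp <- tibble(node = c(swapped, fixed), wave = c("x", "x", "y"),
                 theta = 0, freq = 1, const = FALSE)
    branches$tp <- .new_branch("two-in-phase", with_row2(tp), component$id)
    fs <- tibble(node = c(swapped, fixed), wave = c("x", "x", "z"),
                 theta = c(0, 0.5, 0), freq = c(1, 1, 2), const = FALSE)
    branches$fs <- .new_branch("fused-node standing", with_row2(fs), component$id)
  } else {
    st <- tibble(node = cyc, wave = "a", theta = c(0, 0, 0.5, 0.5),
                 freq = 1, const = FALSE)
    branches$st <- .new_branch("antiphase standing", with_row2(st), component$id)
    fs <- tibble(node = cyc, wave = c("a", "b", "a", "b"),
                 theta = c(0, 0, 0.5, 0), freq = c(1, 2, 1, 2),
                 const = FALSE)
    branches$fs <- .new_branch("fused-node standing", with_row2(fs), component$id)
    rw <- tibble(node = cyc, wave = "a", theta = (seq_len(4) - 1) / 4,
                 freq = 1, const = FALSE)
    branches$rw <- .new_branch("rotating wave", with_row2(rw), component$id)
  }
  unname(branches)
}

#' Combined branch over several flagged one-dimensional components
#'
#' When every fusion-breaking component of a network is of 1-D type and each
#' carries a trivially-acting level swap (so each alone yields only partial
#' fusion), the generic oscillation combines them: one independent wave per
#' component, with the remaining nodes as frequency-2 fused constants. This
#' reproduces the combined states of the multi-level (three-color) networks.
#'
#' @param decomposition Annotated [isotypic_decomposition()].
#' @param group The `symmetry_group`.
#' @param network The [rivalry_network()].
#' @return A `solution_branch`, or `NULL` when the construction does not
#'   apply.
#' @export
combined_branch <- function(decomposition, group, network) {
  flagged <- keep(decomposition$components, \(cp) isTRUE(cp$fusion_breaking))
  if (length(flagged) < 2L) return(NULL)
  if (!all(map_int(flagged, "irrep_dim") == 1L)) return(NULL)
  if (!all(map_lgl(flagged, \(cp) isTRUE(cp$leads_to_fusion)))) return(NULL)
  waves <- c("a", "b", "x", "y", "z")
  rows <- imap(flagged, function(cp, i) {
    v <- cp$basis[, 1]
    nz <- which(abs(v) > 1e-8)
    if (v[nz[1]] < 0) v <- -v
    tibble(node = nz, wave = waves[i],
           theta = ifelse(v[nz] > 0, 0, 0.5), freq = 1, const = FALSE)
  }) |> bind_rows()
  const_nodes <- setdiff(seq_len(group$n), rows$node)
  .new_branch("combined level-swap",
              bind_rows(rows, .const_rows(const_nodes, group)))
}

#' Full branch catalog for a network
#'
#' Convenience wrapper: branches for every fusion-breaking component plus the
#' [combined_branch()] when it applies.
#'
#' @inheritParams combined_branch
#' @return Named list of `solution_branch` lists per component (names
#'   `component_<id>`), plus `combined` when present.
#' @export
branch_catalog <- function(decomposition, group, network) {
  flagged <- keep(decomposition$components, \(cp) isTRUE(cp$fusion_breaking))
  out <- list()
  for (cp in flagged) {
    out[[paste0("component_", cp$id)]] <-
      tryCatch(predict_branches(cp, group, network),
               error = function(e) e$message)
  }
  cb <- combined_branch(decomposition, group, network)
  if (!is.null(cb)) out$combined <- list(cb)
  out
}

#' Spatiotemporal symmetries of a branch on the waveform templates
#'
#' For each group element, finds the temporal phase shift (an exact fraction
#' of the period) under which the element leaves the branch invariant on the
#' waveform templates, if one exists.
#'
#' @param branch A `solution_branch`.
#' @param group The `symmetry_group`.
#' @param template A [waveform_template()].
#' @param tol Residual below which the symmetry is accepted (default 1e-9).
#' @return Tibble with `element`, `theta` (phase shift), `residual`; only
#'   elements admitting an exact shift are listed.
#' @export
branch_symmetry <- function(branch, group, template = waveform_template(),
                            tol = 1e-9) {
  grid <- 0:23 / 24
  tt <- 0:95 / 96
  X <- branch_signals(branch, tt, template)
  rows <- list()
  for (p in group$elements) {
    gX <- X
    gX[p, ] <- X[, ]
    best <- Inf
    best_th <- NA_real_
    for (s in seq_along(grid)) {
      sh <- (s - 1L) * 4L
      Xs <- X[, c(seq(sh + 1L, 96L), seq_len(sh))[seq_len(96L)], drop = FALSE]
      res <- max(abs(gX - Xs))
      if (res < best) { best <- res; best_th <- grid[s] }
    }
    if (best < tol) {
      rows[[length(rows) + 1L]] <- tibble(element = perm_cycles(p),
                                          theta = best_th, residual = best)
    }
  }
  bind_rows(rows)
}
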