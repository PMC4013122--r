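# Small permutation utilities. A permutation on n nodes is an integer vector
# p with p[i] = image of node i. Composition (p %p% q)(i) = p[q[i]].

#' @export
#' @rdname perm_utils
#' @param p,q Integer permutation vectors.
perm_compose <- function(p, q) p[q]

#' @export
#' @rdname perm_utils
perm_inverse <- function(p) order(p)

#' Permutation helpers
#'
#' Cycle notation, composition and inverse for permutations given as integer
#' image vectors.
#'
#' @return `perm_cycles()` returns the cycle-notation string (sorted by
#'   smallest moved point, identity printed as `"()"`).
#' @rdname perm_utils
#' @export
perm_cycles <- function(p) {
  n <- length(p)
  seen <- logical(n)
  out <- character()
  for (i in seq_len(n)) {
    if (seen[i] || p[i] == i) { seen[i] <- TRUE; next }
    cyc <- i
    j <- p[i]
    seen[i] <- TRUE
    while (j != i) { cyc <- c(cyc, j); seen[j] <- TRUE; j <- p[j] }
    out <- c(out, paste0("(", paste(cyc, collapse = " "), ")"))
  }
  if (length(out) == 0L) "()" else paste(out, collapse = "")
}

perm_key <- function(p) paste(p, collapse = ",")

perm_order <- function(p) {
  q <- p
  k <- 1L
  idp <- seq_along(p)
  while (!identical(q, idp)) { q <- perm_compose(p, q); k <- k + 1L }
  k
}

#' Permutation matrix of a node permutation
#'
#' Returns the matrix `P` with `(P x)[p[i]] = x[i]`, i.e. `P[p[i], i] = 1`,
#' so that applying `P` to a state vector moves the value at node `i` to node
#' `p[i]`.
#'
#' @param p Integer permutation vector.
#' @return An n-by-n 0/1 matrix.
#' @export
perm_matrix <- function(p) {
  n <- length(p)
  P <- matrix(0, n, n)
  P[cbind(p, seq_len(n))] <- 1
  P
}

# closure of a set of permutations under composition
perm_closure <- function(gens, n) {
  if (length(gens) == 0L) return(list(seq_len(n)))
  elems <- list(seq_len(n))
  keys <- perm_key(elems[[1]])
  frontier <- elems
  while (length(frontier) > 0L) {
    nxt <- list()
    for (f in frontier) {
      for (g in gens) {
        h <- perm_compose(g, f)
        k <- perm_key(h)
        if (!k %in% keys) {
          keys <- c(keys, k)
          elems <- c(elems, list(h))
          nxt <- c(nxt, list(h))
        }
      }
    }
    frontier <- nxt
  }
  elems
}

# generate all permutations of 1..n (n small); returns list
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (s in sub) {
    for (pos in seq_len(n)) {
      out[[k]] <- append(s, n, after = pos - 1L)
      k <- k + 1L
    }
  }
  out
}
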