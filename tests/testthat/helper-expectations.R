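# Shared helpers: memoised analyses and published reference data.

.an_cache <- new.env(parent = emptyenv())
get_analysis <- function(name) {
  if (is.null(.an_cache[[name]])) .an_cache[[name]] <- analyze(name)
  .an_cache[[name]]
}

# parse a cycle string like "(1 2)(3 4)" into a permutation on n points
cycles_to_perm <- function(s, n) {
  p <- seq_len(n)
  if (s == "()") return(p)
  for (cyc in regmatches(s, gregexpr("\\(([0-9 ]+)\\)", s))[[1]]) {
    pts <- as.integer(strsplit(gsub("[()]", "", cyc), " +")[[1]])
    for (i in seq_along(pts)) {
      p[pts[i]] <- pts[if (i == length(pts)) 1L else i + 1L]
    }
  }
  p
}

span_projector <- function(vectors) {
  B <- qr.Q(qr(do.call(cbind, vectors)))
  tcrossprod(B)
}

component_projector <- function(component) tcrossprod(component$basis)

# index of the isotypic component whose span equals the given vectors
match_component <- function(decomposition, vectors) {
  P <- span_projector(vectors)
  dists <- vapply(decomposition$components,
                  function(cp) max(abs(component_projector(cp) - P)),
                  numeric(1))
  if (min(dists) > 1e-8) return(NA_integer_)
  which.min(dists)
}

# number of kernel elements that preserve the pattern-1 node set (the
# "spatial" part of the kernel, the convention used in the published tables)
spatial_kernel_order <- function(component, network) {
  p1 <- sort(network$patterns$node[network$patterns$pattern ==
                                     min(network$patterns$pattern)])
  sum(vapply(component$kernel, function(p) all(p[p1] %in% p1), logical(1)))
}

# Published Tables 1-2 rows: vectors are node coefficients in id order 1..n,
# re-derived from the printed strings in printed order (x1 x3 x5 [x7] x2 x4
# x6 [x8]). Kernel expectations use the printed generator elements plus the
# spatial-kernel order convention of the tables.
reorder8 <- function(v) v[order(c(1, 3, 5, 7, 2, 4, 6, 8))]
reorder6 <- function(v) v[order(c(1, 3, 5, 2, 4, 6))]

published_components <- list(
  "four-dot-conventional" = list(
    list(vectors = list(reorder8(c(1, 1, 1, 1, -1, -1, -1, -1))),
         spatial_kernel = 8L),                                   # D4
    list(vectors = list(reorder8(c(1, -1, 1, -1, -1, 1, -1, 1)))),
    list(vectors = list(reorder8(c(1, 0, -1, 0, -1, 0, 1, 0)),
                        reorder8(c(0, 1, 0, -1, 0, -1, 0, 1))),
         spatial_kernel = 1L)                                    # 1
  ),
  "four-dot-scrambled-diagonal" = list(
    # the diagonal D4 interleaves row swaps, so the tables' kernel D4 is
    # checked as the full kernel order rather than the row-preserving part
    list(vectors = list(reorder8(c(1, -1, 1, -1, -1, 1, -1, 1))),
         kernel_order = 8L),                                     # D4
    list(vectors = list(reorder8(c(1, 1, 1, 1, -1, -1, -1, -1)))),
    list(vectors = list(reorder8(c(1, 0, -1, 0, -1, 0, 1, 0)),
                        reorder8(c(0, 1, 0, -1, 0, -1, 0, 1))),
         spatial_kernel = 1L)                                    # 1
  ),
  "four-dot-scrambled-adjacent" = list(
    list(vectors = list(reorder8(c(1, 1, 1, 1, -1, -1, -1, -1))),
         spatial_kernel = 4L),                                   # D2
    list(vectors = list(reorder8(c(1, 1, -1, -1, -1, -1, 1, 1))),
         kernel_contains = "(1 3)(5 7)(2 4)(6 8)"),              # Z2(kappa)
    list(vectors = list(reorder8(c(1, -1, -1, 1, -1, 1, 1, -1))),
         kernel_contains = "(1 7)(3 5)(2 8)(4 6)"),              # Z2(tau)
    list(vectors = list(reorder8(c(1, -1, 1, -1, -1, 1, -1, 1))),
         kernel_contains = "(1 5)(2 6)(3 7)(4 8)")               # Z2(kappa*tau)
  ),
  "four-dot-scrambled-unbalanced" = list(
    list(vectors = list(reorder8(c(1, 0, 1, 0, -1, 0, -1, 0)),
                        reorder8(c(0, 1, 0, 0, 0, -1, 0, 0)),
                        reorder8(c(0, 0, 0, 1, 0, 0, 0, -1))),
         kernel_contains = "(1 5)(2 6)"),                        # Z2(sigma)
    list(vectors = list(reorder8(c(1, 0, -1, 0, -1, 0, 1, 0))),
         kernel_contains = "(1 6)(2 5)(3 4)(7 8)")               # Z2(sigma*rho)
  ),
  "three-dot-conventional" = list(
    list(vectors = list(reorder6(c(1, 1, 1, -1, -1, -1))),
         spatial_kernel = 6L),                                   # D3
    list(vectors = list(reorder6(c(1, 0, -1, -1, 0, 1)),
                        reorder6(c(0, 1, -1, 0, -1, 1))),
         spatial_kernel = 1L)                                    # 1
  ),
  "three-dot-scrambled" = list(
    list(vectors = list(reorder6(c(1, 1, 0, -1, -1, 0)),
                        reorder6(c(0, 0, 1, 0, 0, -1))),
         kernel_contains = "(1 3)(2 4)"),                        # Z2(kappa)
    list(vectors = list(reorder6(c(1, -1, 0, -1, 1, 0))),
         kernel_contains = "(1 4)(2 3)(5 6)")                    # Z2(kappa*rho)
  )
)

# published generator cycles per network (all must be group elements)
published_generators <- list(
  "conventional-monkey-text" = "(1 2)",
  "scrambled-monkey-text" = c("(1 2)(3 4)", "(1 3)(2 4)"),
  "shevell-two-gratings" = c("(4 6)(5 7)(3 8)", "(1 2)(4 5)(6 7)"),
  "hong-shevell" = c("(1 3)", "(4 6)"),
  "four-dot-conventional" = "(1 2)(3 4)(5 6)(7 8)",
  "four-dot-scrambled-adjacent" = c("(1 2)(3 4)(5 6)(7 8)",
                                    "(1 3)(5 7)(2 4)(6 8)",
                                    "(1 7)(3 5)(2 8)(4 6)",
                                    "(1 5)(2 6)(3 7)(4 8)"),
  "four-dot-scrambled-unbalanced" = c("(1 2)(3 4)(5 6)(7 8)", "(1 5)(2 6)"),
  "three-dot-conventional" = "(1 2)(3 4)(5 6)",
  "three-dot-scrambled" = c("(1 2)(3 4)(5 6)", "(1 3)(2 4)")
)
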