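test_that("backtracking automorphisms equal the naive enumeration (n <= 8)", {
  small <- c("conventional-monkey-text", "scrambled-monkey-text",
             "hong-shevell", "three-dot-conventional", "three-dot-scrambled",
             "four-dot-conventional", "four-dot-scrambled-unbalanced",
             "shevell-two-gratings")
  for (nm in small) {
    nw <- paper_network(nm)
    fast <- automorphism_group(nw)
    slow <- automorphism_group(nw, method = "naive")
    expect_setequal(fast$keys, slow$keys)
  }
})

test_that("group orders match the published symmetry groups", {
  expected <- c(
    "conventional-monkey-text" = 2L,       # Z2(rho)
    "scrambled-monkey-text" = 4L,          # Z2(kappa) x Z2(rho)
    "shevell-two-gratings" = 4L,           # Z2(tau) x Z2(rho)
    "hong-shevell" = 4L,                   # D2 = Z2(rho) x Z2(tau)
    "four-dot-conventional" = 16L,         # D4 x Z2(rho)
    "four-dot-scrambled-diagonal" = 16L,   # D4 x Z2(rho)
    "four-dot-scrambled-adjacent" = 8L,    # D2 x Z2(rho)
    "four-dot-scrambled-unbalanced" = 4L,  # Z2(sigma) x Z2(rho)
    "three-dot-conventional" = 12L,        # D3 x Z2(rho)
    "three-dot-scrambled" = 4L             # Z2(kappa) x Z2(rho)
  )
  for (nm in names(expected)) {
    expect_equal(get_analysis(nm)$group$order, expected[[nm]], label = nm)
  }
})

test_that("published generator cycles are group elements", {
  for (nm in names(published_generators)) {
    an <- get_analysis(nm)
    for (cyc in published_generators[[nm]]) {
      p <- cycles_to_perm(cyc, an$network$n_nodes)
      expect_true(group_contains(an$group, p),
                  label = paste(nm, cyc))
    }
  }
})

test_that("non-symmetries are rejected", {
  an <- get_analysis("four-dot-scrambled-unbalanced")
  # this column swap is a symmetry of the conventional network but is broken
  # by the unbalanced scrambling
  expect_false(group_contains(an$group, cycles_to_perm("(1 3)(2 4)", 8)))
})

test_that("canonical eye swap matches the published rho", {
  expected_rho <- c(
    "conventional-monkey-text" = "(1 2)",
    "scrambled-monkey-text" = "(1 2)(3 4)",
    "shevell-two-gratings" = "(1 2)(4 5)(6 7)",
    # Hong-Shevell prints rho=(1 3) and tau=(4 6) separately; the canonical
    # element nontrivial in every movable column is their product
    "hong-shevell" = "(1 3)(4 6)",
    "four-dot-conventional" = "(1 2)(3 4)(5 6)(7 8)",
    "three-dot-conventional" = "(1 2)(3 4)(5 6)"
  )
  for (nm in names(expected_rho)) {
    expect_equal(perm_cycles(get_analysis(nm)$rho), expected_rho[[nm]],
                 label = nm)
  }
})

test_that("maximal fusion states have the published synchrony classes", {
  # transitive actions: a single synchrony class
  expect_length(get_analysis("four-dot-conventional")$fusion$classes, 1L)
  expect_length(get_analysis("three-dot-conventional")$fusion$classes, 1L)
  # three-dot scrambled fusion has the form (a a b a a b): two classes
  fus3 <- get_analysis("three-dot-scrambled")$fusion
  expect_length(fus3$classes, 2L)
  expect_setequal(fus3$classes[[which.max(lengths(fus3$classes))]],
                  c(1L, 2L, 3L, 4L))
  # Hong-Shevell: nodes 1,3 equal and 4,6 equal; nodes 2, 5 free
  fus_hs <- get_analysis("hong-shevell")$fusion
  expect_length(fus_hs$classes, 4L)
  expect_true(any(vapply(fus_hs$classes, identical, logical(1), c(1L, 3L))))
  expect_true(any(vapply(fus_hs$classes, identical, logical(1), c(4L, 6L))))
})

test_that("fixed-point subspace basis is orthonormal and invariant", {
  an <- get_analysis("four-dot-scrambled-unbalanced")
  fus <- an$fusion
  B <- fus$basis
  expect_equal(ncol(B), length(fus$classes))
  expect_equal(crossprod(B), diag(ncol(B)), tolerance = 1e-12)
  v <- B %*% runif(ncol(B))
  for (p in an$group$elements) {
    gv <- numeric(length(v)); gv[p] <- v
    expect_equal(gv, as.numeric(v), tolerance = 1e-12)
  }
})

test_that("group naming identifies the published structures", {
  expect_match(get_analysis("four-dot-conventional")$group_name, "^D4 x Z2")
  expect_match(get_analysis("three-dot-conventional")$group_name, "^D3 x Z2")
  expect_match(get_analysis("scrambled-monkey-text")$group_name, "^Z2 x Z2")
})

test_that("permutation utilities are consistent", {
  p <- cycles_to_perm("(1 2 3)(4 5)", 6)
  expect_equal(perm_compose(p, perm_inverse(p)), 1:6)
  expect_equal(perm_order(p), 6L)
  expect_equal(perm_cycles(1:6), "()")
  P <- perm_matrix(p)
  x <- rnorm(6)
  expect_equal(as.numeric(P %*% x)[p], x)
})
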