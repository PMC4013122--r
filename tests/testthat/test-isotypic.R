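test_that("decompositions are complete, orthonormal, and idempotent", {
  for (nm in paper_networks()) {
    an <- get_analysis(nm)
    dec <- an$decomposition
    n <- an$network$n_nodes
    expect_equal(sum(vapply(dec$components, function(cp) cp$dimension,
                            integer(1))), n, label = nm)
    allB <- do.call(cbind, lapply(dec$components, function(cp) cp$basis))
    expect_lt(max(abs(crossprod(allB) - diag(n))), 1e-8)
    for (cp in dec$components) {
      P <- component_projector(cp)
      expect_lt(max(abs(P %*% P - P)), 1e-8)
    }
    # component projectors sum to the identity
    Psum <- Reduce(`+`, lapply(dec$components, component_projector))
    expect_lt(max(abs(Psum - diag(n))), 1e-8)
  }
})

test_that("the decomposition is independent of the random draw", {
  for (nm in c("four-dot-conventional", "hong-shevell",
               "three-dot-conventional")) {
    d0 <- get_analysis(nm)$decomposition
    d1 <- isotypic_decomposition(get_analysis(nm)$group, seed = 987654L)
    expect_equal(length(d0$components), length(d1$components))
    for (k in seq_along(d0$components)) {
      expect_lt(max(abs(component_projector(d0$components[[k]]) -
                          component_projector(d1$components[[k]]))), 1e-7)
    }
  }
})

test_that("components are invariant subspaces with consistent sign maps", {
  an <- get_analysis("four-dot-scrambled-adjacent")
  Ps <- lapply(an$group$elements, perm_matrix)
  for (cp in an$decomposition$components) {
    B <- cp$basis
    for (i in seq_along(Ps)) {
      act <- crossprod(B, Ps[[i]] %*% B)
      expect_lt(max(abs(Ps[[i]] %*% B - B %*% act)), 1e-7)
      if (cp$sign[i] == 1L) {
        expect_lt(max(abs(act - diag(ncol(B)))), 1e-6)
      } else if (cp$sign[i] == -1L) {
        expect_lt(max(abs(act + diag(ncol(B)))), 1e-6)
      }
    }
  }
})

test_that("fusion-breaking component counts match the published analysis", {
  expected <- c(
    "conventional-monkey-text" = 1L,
    "scrambled-monkey-text" = 2L,
    "four-dot-conventional" = 3L,
    "four-dot-scrambled-diagonal" = 3L,
    "four-dot-scrambled-adjacent" = 4L,
    "four-dot-scrambled-unbalanced" = 2L,
    "three-dot-conventional" = 2L,
    "three-dot-scrambled" = 2L,
    "hong-shevell" = 2L,
    "shevell-two-gratings" = 2L
  )
  for (nm in names(expected)) {
    tb <- tidy(get_analysis(nm)$decomposition)
    expect_equal(sum(tb$fusion_breaking), expected[[nm]], label = nm)
    expect_equal(sum(tb$sign_rho == 0L), 0L, label = nm)
  }
})

test_that("published table rows match components and kernels row-for-row", {
  for (nm in names(published_components)) {
    an <- get_analysis(nm)
    dec <- an$decomposition
    rho_i <- match(paste(an$rho, collapse = ","), an$group$keys)
    for (row in published_components[[nm]]) {
      idx <- match_component(dec, row$vectors)
      expect_false(is.na(idx), label = paste(nm, "row matched"))
      cp <- dec$components[[idx]]
      # every table row lies where rho acts as minus the identity
      expect_equal(cp$sign[rho_i], -1L, label = paste(nm, "sign of rho"))
      expect_true(isTRUE(cp$fusion_breaking))
      if (!is.null(row$kernel_contains)) {
        p <- cycles_to_perm(row$kernel_contains, an$network$n_nodes)
        in_ker <- any(vapply(cp$kernel, identical, logical(1), p))
        expect_true(in_ker, label = paste(nm, row$kernel_contains))
      }
      if (!is.null(row$spatial_kernel)) {
        expect_equal(spatial_kernel_order(cp, an$network), row$spatial_kernel,
                     label = paste(nm, "spatial kernel order"))
      }
      if (!is.null(row$kernel_order)) {
        expect_length(cp$kernel, row$kernel_order)
      }
    }
  }
})

test_that("kernel labels are recognizable subgroups", {
  an <- get_analysis("three-dot-conventional")
  tb <- tidy(an$decomposition)
  flagged <- tb[tb$fusion_breaking, ]
  expect_setequal(flagged$kernel[flagged$dim_per_k == 1], "D3")
  # the 2-D standard D3 representation is faithful on the full group
  expect_equal(flagged$kernel[flagged$dim_per_k == 2], "1")
})

test_that("level-swap components are annotated as leading to fusion", {
  tb <- tidy(get_analysis("hong-shevell")$decomposition)
  expect_true(all(tb$leads_to_fusion[tb$fusion_breaking]))
  tb4 <- tidy(get_analysis("four-dot-conventional")$decomposition)
  expect_false(any(tb4$leads_to_fusion[tb4$fusion_breaking]))
})

test_that("decomposition_report merges the eye-swap-trivial block", {
  rep4 <- decomposition_report(get_analysis("four-dot-conventional")$decomposition)
  expect_equal(sort(rep4$dim_per_k), c(1L, 1L, 2L, 4L))
  expect_equal(sum(is.na(rep4$component)), 1L)
  raw <- isotypic_decomposition(get_analysis("four-dot-conventional")$group)
  expect_error(decomposition_report(raw), "not annotated")
})

test_that("component_kernel returns a labeled subgroup", {
  an <- get_analysis("four-dot-conventional")
  cp <- an$decomposition$components[[which(tidy(an$decomposition)$kernel == "D4")[1]]]
  ker <- component_kernel(cp, an$group)
  expect_s3_class(ker, "symmetry_group")
  expect_equal(ker$order, 8L)
  expect_equal(attr(ker, "label"), "D4")
})
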