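test_that("two-node network yields the classic rivalry branch", {
  an <- get_analysis("conventional-monkey-text")
  expect_length(an$branches, 1L)
  b <- an$branches[[1]][[1]]
  expect_equal(b$name, "pure antiphase")
  pat <- tidy(b)
  expect_equal(pat$theta[order(pat$node)], c(0, 0.5))
  # the eye swap is a half-period spatiotemporal symmetry of the branch
  bs <- branch_symmetry(b, an$group)
  expect_equal(bs$theta[bs$element == "(1 2)"], 0.5)
})

test_that("three-dot conventional predicts Eq (9) and the three D3 types", {
  an <- get_analysis("three-dot-conventional")
  tb <- tidy(an$decomposition)
  id1 <- tb$component[tb$fusion_breaking & tb$dim_per_k == 1]
  id2 <- tb$component[tb$fusion_breaking & tb$dim_per_k == 2]
  b1 <- an$branches[[paste0("component_", id1)]]
  expect_length(b1, 1L)
  pat <- tidy(b1[[1]])
  # (x0 x0 x0 x1/2 x1/2 x1/2) in node order 1..6 (odd = left eye)
  expect_equal(pat$theta[order(pat$node)], c(0, .5, 0, .5, 0, .5))
  expect_true(all(!pat$const))

  b2 <- an$branches[[paste0("component_", id2)]]
  expect_setequal(vapply(b2, function(b) b$name, character(1)),
                  c("rotating wave", "two-in-phase", "fused-node standing"))
  rw <- b2[[which(vapply(b2, function(b) b$name, character(1)) ==
                    "rotating wave")]]
  rpat <- tidy(rw)
  # thirds of a period on one eye, half-period shifted on the other
  odd <- rpat[rpat$node %in% c(1, 3, 5), ]
  expect_setequal(round(odd$theta, 6), round(c(0, 1/3, 2/3), 6))
  even <- rpat[rpat$node %in% c(2, 4, 6), ]
  expect_setequal(round(even$theta, 6), round(c(1/2, 5/6, 1/6), 6))
  # spatiotemporal symmetries: the 3-cycle acts as a third-period shift
  bs <- branch_symmetry(rw, an$group)
  rot <- bs[bs$element == "(1 3 5)(2 4 6)", ]
  expect_equal(nrow(rot), 1L)
  expect_true(abs(rot$theta - 1/3) < 1e-9 || abs(rot$theta - 2/3) < 1e-9)
  # fused-node standing contains a double-frequency node pair
  fs <- b2[[which(vapply(b2, function(b) b$name, character(1)) ==
                    "fused-node standing")]]
  expect_equal(sum(tidy(fs)$freq == 2), 2L)
})

test_that("four-dot conventional V2- predicts the three published D4 types", {
  an <- get_analysis("four-dot-conventional")
  tb <- tidy(an$decomposition)
  id2 <- tb$component[tb$fusion_breaking & tb$dim_per_k == 2]
  bl <- an$branches[[paste0("component_", id2)]]
  nms <- vapply(bl, function(b) b$name, character(1))
  expect_setequal(nms, c("antiphase standing", "fused-node standing",
                         "rotating wave"))
  rw <- bl[[which(nms == "rotating wave")]]
  rpat <- tidy(rw)
  row1 <- sort(an$network$patterns$node[an$network$patterns$pattern ==
                                          min(an$network$patterns$pattern)])
  expect_setequal(round(rpat$theta[rpat$node %in% row1], 6),
                  round(c(0, 1/4, 2/4, 3/4), 6))
  # published fusion branch (a0 b0 a1/2 b0 ...): b at double frequency
  fs <- bl[[which(nms == "fused-node standing")]]
  expect_equal(sum(tidy(fs)$freq == 2), 4L)
  expect_equal(length(unique(tidy(fs)$wave)), 2L)
})

test_that("every branch is consistent with its component sign map", {
  an <- get_analysis("four-dot-conventional")
  for (bl in an$branches) {
    if (!is.list(bl)) next
    for (b in bl) {
      bs <- branch_symmetry(b, an$group)
      # the identity is always a symmetry at zero shift
      expect_equal(bs$theta[bs$element == "()"], 0)
      # the eye swap acts with a half-period shift on every branch
      rho_cy <- perm_cycles(an$rho)
      expect_equal(bs$theta[bs$element == rho_cy], 0.5)
    }
  }
})

test_that("branch percept sequences alternate the learned patterns", {
  an <- get_analysis("conventional-monkey-text")
  ps <- percept_sequence(an$branches[[1]][[1]], an$network)
  expect_equal(nrow(tidy(ps)), 2L)
  expect_setequal(tidy(ps)$image, c("monkey", "text"))
})

test_that("Hong-Shevell combined branch gives the four published cases", {
  an <- get_analysis("hong-shevell")
  expect_named(an$branches, c("component_1", "component_2", "combined"),
               ignore.order = TRUE)
  cb <- an$branches$combined[[1]]
  cases <- enumerate_alternation_cases(cb, an$network)
  expect_length(cases, 4L)
  seqs <- lapply(cases, function(ps) tidy(ps))
  lens <- sort(vapply(seqs, nrow, integer(1)))
  # both gray; one eye alternates (x2); both alternate interleaved
  expect_equal(lens, c(1L, 2L, 2L, 4L))
  four <- seqs[[which(vapply(seqs, nrow, integer(1)) == 4L)]]
  percepts <- paste(four[["color-left"]], four[["color-right"]], sep = "/")
  expect_setequal(percepts, c("blue/blue", "orange/blue", "orange/orange",
                              "blue/orange"))
})

test_that("combined branch only applies to multi-component level-swap cases", {
  an <- get_analysis("four-dot-conventional")
  expect_null(combined_branch(an$decomposition, an$group, an$network))
  expect_false("combined" %in% names(an$branches))
})

test_that("predict_branches refuses non-flagged components", {
  an <- get_analysis("four-dot-conventional")
  tb <- tidy(an$decomposition)
  cp <- an$decomposition$components[[tb$component[!tb$fusion_breaking][1]]]
  expect_error(predict_branches(cp, an$group, an$network), "not flagged")
})

test_that("waveform rendering honors offsets and frequencies", {
  an <- get_analysis("three-dot-conventional")
  tb <- tidy(an$decomposition)
  id2 <- tb$component[tb$fusion_breaking & tb$dim_per_k == 2]
  bl <- an$branches[[paste0("component_", id2)]]
  nms <- vapply(bl, function(b) b$name, character(1))
  fs <- bl[[which(nms == "fused-node standing")]]
  t <- 0:63 / 64
  X <- rivalnet:::branch_signals(fs, t)
  pat <- tidy(fs)
  dbl <- pat$node[pat$freq == 2][1]
  # double-frequency nodes repeat after half a period
  expect_equal(X[dbl, 1:32], X[dbl, 33:64], tolerance = 1e-12)
})
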