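test_that("the rate model is exactly equivariant for symmetric inputs", {
  for (nm in c("hong-shevell", "four-dot-conventional")) {
    an <- get_analysis(nm)
    m <- rate_model(an$network)
    expect_lt(equivariance_check(m, an$group, trials = 25), 1e-10)
  }
})

test_that("asymmetric inputs break equivariance measurably", {
  an <- get_analysis("conventional-monkey-text")
  I <- c(1, 1.05)
  m <- rate_model(an$network, rate_params(I = I))
  expect_gt(equivariance_check(m, an$group, trials = 10), 1e-3)
  expect_error(find_fusion_equilibrium(m, an$group), "not symmetric")
})

test_that("model construction validates parameters and weights", {
  nw <- paper_network("four-dot-conventional")
  expect_error(rate_model(nw, rate_params(epsilon = 2)), "epsilon")
  expect_error(rate_model(nw, rate_params(beta = -1)), "beta")
  expect_error(rate_model(nw, rate_params(w = c(nope = 0.5))), "missing")
  classes <- sort(unique(nw$excitatory$class))
  w <- stats::setNames(c(0.5, 0.9), classes)
  m <- rate_model(nw, rate_params(w = w))
  expect_equal(sort(unique(m$params$w)), c(0.5, 0.9))
})

test_that("fusion equilibria solve the full system to 1e-10", {
  for (nm in c("conventional-monkey-text", "three-dot-conventional",
               "four-dot-conventional", "hong-shevell")) {
    an <- get_analysis(nm)
    m <- rate_model(an$network)
    eq <- find_fusion_equilibrium(m, an$group)
    expect_lt(attr(eq, "residual"), 1e-10)
    # the equilibrium lies in the fixed-point subspace
    E <- eq[seq_len(m$n)]
    for (cl in an$fusion$classes) {
      expect_lt(diff(range(E[cl])), 1e-12)
    }
  }
})

test_that("Jacobian blocks conserve the dense spectrum", {
  for (nm in c("three-dot-conventional", "shevell-two-gratings",
               "four-dot-scrambled-adjacent")) {
    an <- get_analysis(nm)
    m <- rate_model(an$network)
    eq <- find_fusion_equilibrium(m, an$group)
    sp <- isotypic_jacobian_spectrum(m, eq, an$decomposition)
    expect_lt(sp$off_block, 1e-9)
    block_union <- unlist(sp$blocks)
    expect_lt(rivalnet:::spectrum_distance(block_union, sp$full), 1e-7)
  }
})

test_that("two-node linearization matches the closed-form antiphase block", {
  an <- get_analysis("conventional-monkey-text")
  m <- rate_model(an$network)
  p <- m$params
  eq <- find_fusion_equilibrium(m, an$group)
  E <- eq[1]
  u <- p$I - p$beta * E - p$g * E
  a <- p$gain$dg(u)
  A2 <- rbind(c((-1 + a * p$beta) / p$epsilon, -a * p$g / p$epsilon),
              c(1, -1))
  closed <- eigen(A2, only.values = TRUE)$values
  sp <- isotypic_jacobian_spectrum(m, eq, an$decomposition)
  tb <- tidy(an$decomposition)
  anti <- sp$blocks[[paste0("component_", tb$component[tb$fusion_breaking])]]
  expect_lt(rivalnet:::spectrum_distance(closed, anti), 1e-8)
  # the symmetric (fusion) block has the remaining eigenvalues
  sym <- sp$blocks[[paste0("component_", tb$component[!tb$fusion_breaking])]]
  A2s <- rbind(c((-1 - a * p$beta) / p$epsilon, -a * p$g / p$epsilon),
               c(1, -1))
  expect_lt(rivalnet:::spectrum_distance(
    eigen(A2s, only.values = TRUE)$values, sym), 1e-8)
})

test_that("hopf_scan locates the fusion-breaking crossing in g", {
  an <- get_analysis("conventional-monkey-text")
  m <- rate_model(an$network)
  hs <- hopf_scan(m, "g", c(3, 5), steps = 9, group = an$group,
                  decomposition = an$decomposition)
  expect_equal(nrow(hs$crossings), 1L)
  cr <- hs$crossings
  expect_gt(cr$omega, 0)
  # at the crossing the closed-form Hopf condition a*beta = 1 + eps holds
  mstar <- rate_model(an$network, rate_params(g = cr$value))
  eq <- find_fusion_equilibrium(mstar, an$group)
  p <- mstar$params
  u <- p$I - p$beta * eq[1] - p$g * eq[1]
  a <- p$gain$dg(u)
  expect_lt(abs(a * p$beta - (1 + p$epsilon)), 1e-4)
})

test_that("the fixed-point subspace is flow-invariant over 100 time units", {
  an <- get_analysis("three-dot-conventional")
  # transversally stable fusion (gain sigma = 2), so roundoff off the
  # invariant subspace is not exponentially amplified
  m <- rate_model(an$network, rate_params(gain = gain_naka_rushton(2)))
  state0 <- c(rep(0.8, m$n), rep(0.1, m$n))  # symmetric, far from equilibrium
  traj <- integrate_model(m, state0, duration = 100, dt = 0.1)
  E <- traj$state[, seq_len(m$n)]
  H <- traj$state[, m$n + seq_len(m$n)]
  drift <- max(apply(E, 1, function(r) diff(range(r))),
               apply(H, 1, function(r) diff(range(r))))
  expect_lt(drift, 1e-6)
})

test_that("realized oscillation matches the predicted branch symmetries", {
  an <- get_analysis("conventional-monkey-text")
  sim <- simulate_rivalry(an, duration = 250)
  expect_true(sim$spatiotemporal$periodic)
  st <- tidy(sim$spatiotemporal)
  predicted <- branch_symmetry(an$branches[[1]][[1]], an$group)
  for (k in seq_len(nrow(predicted))) {
    row <- st[st$element == predicted$element[k], ]
    expect_lt(row$residual, 0.01)
    dtheta <- abs(row$theta - predicted$theta[k])
    expect_lt(min(dtheta, 1 - dtheta), 0.02)
  }
  expect_equal(nrow(tidy(sim$dominance)), 2L)
  expect_setequal(tidy(sim$dominance)$image, c("monkey", "text"))
})

test_that("three-dot simulation realizes the pure antiphase branch", {
  an <- get_analysis("three-dot-conventional")
  sim <- simulate_rivalry(an, duration = 250)
  st <- tidy(sim$spatiotemporal)
  ok <- st[st$residual < 0.01, ]
  rho_row <- ok[ok$element == perm_cycles(an$rho), ]
  expect_equal(nrow(rho_row), 1L)
  dtheta <- abs(rho_row$theta - 0.5)
  expect_lt(min(dtheta, 1 - dtheta), 0.02)
  # all three dots alternate together between the two colors
  dom <- tidy(sim$dominance)
  expect_equal(nrow(dom), 2L)
  expect_true(all(dom$UL == dom$LL & dom$LL == dom$R))
})

test_that("period estimation flags non-oscillating trajectories", {
  an <- get_analysis("conventional-monkey-text")
  m <- rate_model(an$network, rate_params(g = 5))  # past restabilization
  eq <- find_fusion_equilibrium(m, an$group)
  traj <- integrate_model(m, as.numeric(eq) + 1e-3, duration = 60, dt = 0.05)
  expect_true(is.na(estimate_period(traj)))
  cls <- classify_spatiotemporal(traj, an$group)
  expect_false(cls$periodic)
})

test_that("integration rejects bad initial states", {
  m <- rate_model(paper_network("conventional-monkey-text"))
  expect_error(integrate_model(m, c(NA, 0, 0, 0), 1), "finite")
  expect_error(integrate_model(m, c(0.1, 0.1), 1), "wrong length")
})
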