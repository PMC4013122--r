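# Generalized Wilson rate equations on a rivalry network. Each node carries
# an activity variable E and a fatigue variable H (internal dimension k = 2):
#   eps * dE/dt = -E + G(I + sum_exc w_c E_src - beta * sum_rivals E - g H)
#   dH/dt       =  E - H
# with one excitatory weight per arrow class (equal weights recover the
# classical single-w model and enlarge the symmetry group).

#' Gain functions
#'
#' `gain_naka_rushton()` is the default firing-rate gain
#' `G(z) = z^2 / (sigma^2 + z^2)` for `z > 0` (0 otherwise), standard in the
#' rivalry-model literature; `gain_sigmoid()` is
#' `1 / (1 + exp(-lambda (z - theta0)))`. Both are nonnegative and
#' nondecreasing and carry their analytic derivative.
#'
#' @param sigma Semi-saturation constant (> 0).
#' @return A `gain_function`: list with `g`, `dg`, `name`.
#' @export
gain_naka_rushton <- function(sigma = 1) {
  stopifnot(sigma > 0)
  structure(list(
    g = function(z) ifelse(z > 0, z^2 / (sigma^2 + z^2), 0),
    dg = function(z) ifelse(z > 0, 2 * sigma^2 * z / (sigma^2 + z^2)^2, 0),
    name = sprintf("naka-rushton(sigma=%g)", sigma)
  ), class = "gain_function")
}

#' @rdname gain_naka_rushton
#' @param lambda Slope.
#' @param theta0 Threshold.
#' @export
gain_sigmoid <- function(lambda = 10, theta0 = 1) {
  structure(list(
    g = function(z) 1 / (1 + exp(-lambda * (z - theta0))),
    dg = function(z) {
      s <- 1 / (1 + exp(-lambda * (z - theta0)))
      lambda * s * (1 - s)
    },
    name = sprintf("sigmoid(lambda=%g, theta0=%g)", lambda, theta0)
  ), class = "gain_function")
}

#' Default rate-model parameters
#'
#' Time-scale ratio `epsilon`, fatigue strength `g`, inhibition weight
#' `beta`, excitatory class weights `w` (scalar applied to every class, or a
#' vector named by class label), external input `I` (scalar or per-node), and
#' the gain. The defaults place the two-node model past its fusion-breaking
#' Hopf bifurcation, so rivalry oscillations are realized out of the box.
#'
#' @param epsilon Time-scale ratio (0 < epsilon < 1).
#' @param g Fatigue strength (> 0).
#' @param beta Reciprocal inhibition weight (> 0).
#' @param w Excitatory weight(s) (> 0).
#' @param I External input (>= 0).
#' @param gain A gain function.
#' @return A parameter list.
#' @export
rate_params <- function(epsilon = 0.1, g = 2, beta = 2, w = 0.75, I = 1,
                        gain = gain_naka_rushton()) {
  list(epsilon = epsilon, g = g, beta = beta, w = w, I = I, gain = gain)
}

#' Build a rate-equation model on a rivalry network
#'
#' @param network A [rivalry_network()].
#' @param params A [rate_params()] list. `w` must cover every excitatory
#'   class (scalar, or named by the class labels of
#'   [excitatory_arrow_classes()]). Arrows of multiplicity p contribute
#'   `p * w_c`.
#' @return Object of class `rate_model`: the network, parameters, the
#'   excitatory and inhibitory coupling matrices, and node inputs.
#' @export
rate_model <- function(network, params = rate_params()) {
  stopifnot(inherits(network, "rivalry_network"))
  n <- network$n_nodes
  if (!is.numeric(params$epsilon) || params$epsilon <= 0 || params$epsilon >= 1)
    abort("epsilon must be in (0, 1)")
  if (params$g <= 0) abort("g must be positive")
  if (params$beta <= 0) abort("beta must be positive")
  if (any(params$I < 0)) abort("inputs I must be nonnegative")
  classes <- sort(unique(network$excitatory$class))
  w <- params$w
  if (length(classes) > 0L) {
    if (length(w) == 1L && is.null(names(w))) {
      w <- setNames(rep(w, length(classes)), classes)
    }
    missing_w <- setdiff(classes, names(w))
    if (length(missing_w) > 0L) {
      abort(paste0("missing excitatory class weight(s): ",
                   paste(missing_w, collapse = "; ")))
    }
    if (any(w[classes] <= 0)) abort("excitatory weights must be positive")
  }
  Wexc <- matrix(0, n, n)
  exc <- network$excitatory
  for (r in seq_len(nrow(exc))) {
    wt <- unname(w[[exc$class[r]]]) * exc$multiplicity[r]
    # arrow tail feeds head; undirected arrows feed both ways
    Wexc[exc$to[r], exc$from[r]] <- Wexc[exc$to[r], exc$from[r]] + wt
    if (!exc$directed[r]) {
      Wexc[exc$from[r], exc$to[r]] <- Wexc[exc$from[r], exc$to[r]] + wt
    }
  }
  Winh <- matrix(0, n, n)
  inh <- network$inhibitory
  for (r in seq_len(nrow(inh))) {
    Winh[inh$to[r], inh$from[r]] <- 1
    Winh[inh$from[r], inh$to[r]] <- 1
  }
  Ivec <- if (length(params$I) == 1L) rep(params$I, n) else params$I
  if (length(Ivec) != n) abort("I must be scalar or length n_nodes")
  params$w <- w
  structure(
    list(network = network, params = params, Wexc = Wexc, Winh = Winh,
         I = Ivec, n = n, state_dim = 2L * n),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model> ", x$n, " nodes (state dimension ", x$state_dim, ")\n",
      "  gain ", x$params$gain$name,
      sprintf("; epsilon=%g g=%g beta=%g", x$params$epsilon, x$params$g,
              x$params$beta), "\n", sep = "")
  invisible(x)
}

# right-hand side on state c(E, H)
model_rhs <- function(model, state) {
  n <- model$n
  E <- state[seq_len(n)]
  H <- state[n + seq_len(n)]
  p <- model$params
  u <- model$I + drop(model$Wexc %*% E) - p$beta * drop(model$Winh %*% E) -
    p$g * H
  c((-E + p$gain$g(u)) / p$epsilon, E - H)
}

# analytic Jacobian at a state
model_jacobian <- function(model, state) {
  n <- model$n
  E <- state[seq_len(n)]
  H <- state[n + seq_len(n)]
  p <- model$params
  u <- model$I + drop(model$Wexc %*% E) - p$beta * drop(model$Winh %*% E) -
    p$g * H
  Dg <- diag(p$gain$dg(u), n)
  A <- (-diag(n) + Dg %*% (model$Wexc - p$beta * model$Winh)) / p$epsilon
  B <- -p$g * Dg / p$epsilon
  rbind(cbind(A, B), cbind(diag(n), -diag(n)))
}

# lift a node permutation to the (E, H) state space
state_perm <- function(p) c(p, length(p) + p)

#' Equivariance residual of a model under its symmetry group
#'
#' Checks `f(gamma x) = gamma f(x)` at random states for every group
#' element; the residual is at machine precision for symmetric inputs by
#' construction, and positive when a perturbed input breaks the symmetry.
#'
#' @param model A [rate_model()].
#' @param group A `symmetry_group` (or list of permutations).
#' @param trials Number of random states (default 100).
#' @param seed RNG seed.
#' @return Maximum residual (sup norm).
#' @export
equivariance_check <- function(model, group, trials = 100L, seed = 0L) {
  elems <- if (inherits(group, "symmetry_group")) group$elements else group
  states <- .with_seed(seed, map(seq_len(trials),
                                 \(i) runif(model$state_dim, -1, 2)))
  worst <- 0
  for (x in states) {
    fx <- model_rhs(model, x)
    for (p in elems) {
      sp <- state_perm(p)
      gx <- numeric(length(x))
      gx[sp] <- x
      fgx <- model_rhs(model, gx)
      gfx <- numeric(length(fx))
      gfx[sp] <- fx
      worst <- max(worst, max(abs(fgx - gfx)))
    }
  }
  worst
}

#' Fusion equilibrium of a symmetric rate model
#'
#' Solves the reduced equilibrium system on the synchrony classes of the
#' group (one activity unknown per node orbit; fatigue equals activity at
#' equilibrium) by damped Newton iteration, and returns the full state in
#' the fixed-point subspace.
#'
#' @param model A [rate_model()] with inputs constant on node orbits.
#' @param group The network's `symmetry_group`.
#' @param tol Residual tolerance on the full right-hand side (default 1e-10).
#' @param max_iter Newton iteration cap.
#' @return Equilibrium state vector (length 2n) with attribute `residual`.
#' @export
find_fusion_equilibrium <- function(model, group, tol = 1e-10,
                                    max_iter = 200L) {
  orbs <- node_orbits(group)
  cls <- integer(model$n)
  for (i in seq_along(orbs)) cls[orbs[[i]]] <- i
  if (any(map_dbl(orbs, \(o) diff(range(model$I[o]))) > 0)) {
    abort("inputs are not symmetric (not constant on node orbits)")
  }
  m <- length(orbs)
  reps <- map_int(orbs, min)
  fullstate <- function(e) {
    E <- e[cls]
    c(E, E)
  }
  red <- function(e) model_rhs(model, fullstate(e))[reps]
  resid <- Inf
  for (e in list(rep(0.2, m), rep(0.05, m), rep(0.5, m), rep(0.9, m))) {
    for (it in seq_len(max_iter)) {
      r <- red(e)
      if (max(abs(r)) < tol / 10) break
      # finite-difference Jacobian of the reduced system (m is tiny)
      J <- matrix(0, m, m)
      h <- 1e-7
      for (j in seq_len(m)) {
        ep <- e; ep[j] <- ep[j] + h
        em <- e; em[j] <- em[j] - h
        J[, j] <- (red(ep) - red(em)) / (2 * h)
      }
      step <- tryCatch(solve(J, r), error = function(err) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        e2 <- e - lam * step
        if (max(abs(red(e2))) < max(abs(r)) || lam < 1e-6) break
        lam <- lam / 2
      }
      e <- e2
    }
    x <- fullstate(e)
    resid <- max(abs(model_rhs(model, x)))
    if (resid < tol) {
      attr(x, "residual") <- resid
      return(x)
    }
  }
  abort(paste0("fusion equilibrium did not converge; last residual ",
               format(resid)))
}

#' Jacobian spectrum by isotypic component
#'
#' Projects the Jacobian at an equilibrium onto each isotypic component
#' (tensored with the internal (E, H) dimensions) and returns the block
#' spectra; the union of block spectra equals the dense spectrum and the
#' off-block coupling vanishes, both within tolerance.
#'
#' @param model A [rate_model()].
#' @param equilibrium State vector (residual < 1e-8).
#' @param decomposition An [isotypic_decomposition()].
#' @param tol Block-diagonalization tolerance (default 1e-7).
#' @return List with `blocks` (per-component eigenvalues), `full`
#'   (dense-Jacobian eigenvalues), `off_block` (max off-block coupling).
#' @export
isotypic_jacobian_spectrum <- function(model, equilibrium, decomposition,
                                       tol = 1e-7) {
  if (max(abs(model_rhs(model, equilibrium))) > 1e-8) {
    abort("state is not an equilibrium (residual above 1e-8)")
  }
  J <- model_jacobian(model, equilibrium)
  lift <- function(B) {
    Z <- matrix(0, nrow(B), ncol(B))
    rbind(cbind(B, Z), cbind(Z, B))
  }
  Qs <- map(decomposition$components, \(cp) lift(cp$basis))
  blocks <- map(Qs, \(Q) eigen(crossprod(Q, J %*% Q), only.values = TRUE)$values)
  off <- 0
  for (i in seq_along(Qs)) {
    for (j in seq_along(Qs)) {
      if (i == j) next
      off <- max(off, max(abs(crossprod(Qs[[i]], J %*% Qs[[j]]))))
    }
  }
  if (off > tol) {
    abort(paste0("block-diagonalization failed: off-block coupling ",
                 format(off), " exceeds tolerance (symmetry inconsistency)"))
  }
  full <- eigen(J, only.values = TRUE)$values
  list(blocks = setNames(blocks,
                         paste0("component_",
                                map_int(decomposition$components, "id"))),
       full = full, off_block = off)
}

# max eigenvalue pairing distance between two spectra of equal size
# (greedy nearest-neighbor matching; robust to ordering ties)
spectrum_distance <- function(a, b) {
  if (length(a) != length(b)) return(Inf)
  a <- as.complex(a)
  b <- as.complex(b)
  used <- logical(length(b))
  worst <- 0
  for (x in a[order(Re(a), Im(a))]) {
    d <- Mod(x - b)
    d[used] <- Inf
    k <- which.min(d)
    used[k] <- TRUE
    worst <- max(worst, d[k])
  }
  worst
}

.update_param <- function(model, param, value) {
  p <- model$params
  if (param %in% c("epsilon", "g", "beta", "I")) {
    p[[param]] <- value
  } else if (param == "w") {
    p$w <- setNames(rep(value, length(p$w)), names(p$w))
  } else if (startsWith(param, "w:")) {
    cls <- sub("^w:", "", param)
    if (!cls %in% names(p$w)) abort(paste0("unknown excitatory class: ", cls))
    p$w[[cls]] <- value
  } else {
    abort(paste0("unsupported scan parameter: ", param))
  }
  rate_model(model$network, p)
}

#' Scan a parameter for fusion-breaking Hopf points
#'
#' Tracks, along a one-parameter scan, the leading eigenvalue (largest real
#' part among complex pairs) of each isotypic Jacobian block at the fusion
#' equilibrium, records sign changes, and refines each crossing by bisection.
#'
#' @param model A [rate_model()].
#' @param param One of `"beta"`, `"g"`, `"epsilon"`, `"I"`, `"w"`, or
#'   `"w:<class>"`.
#' @param range Length-2 numeric scan range.
#' @param steps Number of grid points (default 25).
#' @param group,decomposition Optional precomputed symmetry objects.
#' @param refine_tol Bisection tolerance in the parameter (default 1e-6).
#' @return List with `scan` (tibble of leading complex eigenvalues per
#'   component and grid point; `NA` rows mark equilibrium failures) and
#'   `crossings` (tibble: `param`, `value`, `component`, `omega`).
#' @export
hopf_scan <- function(model, param, range, steps = 25L, group = NULL,
                      decomposition = NULL, refine_tol = 1e-6) {
  if (is.null(group)) group <- automorphism_group(model$network)
  if (is.null(decomposition)) decomposition <- isotypic_decomposition(group)
  grid <- seq(range[1], range[2], length.out = steps)
  comp_ids <- paste0("component_", map_int(decomposition$components, "id"))
  lead <- function(value) {
    m <- .update_param(model, param, value)
    eq <- tryCatch(find_fusion_equilibrium(m, group), error = function(e) NULL)
    if (is.null(eq)) return(NULL)
    sp <- isotypic_jacobian_spectrum(m, eq, decomposition)
    map(sp$blocks, function(ev) {
      cplx <- ev[abs(Im(ev)) > 1e-8]
      if (length(cplx) == 0L) return(c(re = NA_real_, im = NA_real_))
      k <- which.max(Re(cplx))
      c(re = Re(cplx[k]), im = abs(Im(cplx[k])))
    })
  }
  scan <- map(grid, function(v) {
    lv <- lead(v)
    tibble(value = v, component = comp_ids,
           re = if (is.null(lv)) NA_real_ else map_dbl(lv, "re"),
           im = if (is.null(lv)) NA_real_ else map_dbl(lv, "im"))
  }) |> bind_rows()
  crossings <- list()
  for (cid in comp_ids) {
    sub <- scan |> filter(.data$component == cid, !is.na(.data$re))
    if (nrow(sub) < 2L) next
    sgn <- sign(sub$re)
    for (k in which(sgn[-1] * sgn[-length(sgn)] < 0)) {
      lo <- sub$value[k]
      hi <- sub$value[k + 1]
      flo <- sub$re[k]
      while (hi - lo > refine_tol) {
        mid <- (lo + hi) / 2
        lm <- lead(mid)
        if (is.null(lm) || is.na(lm[[cid]][["re"]])) break
        if (sign(lm[[cid]][["re"]]) == sign(flo)) {
          lo <- mid
          flo <- lm[[cid]][["re"]]
        } else {
          hi <- mid
        }
      }
      lm <- lead((lo + hi) / 2)
      crossings[[length(crossings) + 1L]] <- tibble(
        param = param, value = (lo + hi) / 2, component = cid,
        omega = if (is.null(lm)) NA_real_ else unname(lm[[cid]][["im"]])
      )
    }
  }
  list(scan = scan,
       crossings = if (length(crossings)) bind_rows(crossings) else
         tibble(param = character(), value = numeric(),
                component = character(), omega = numeric()))
}

#' Integrate a rate model
#'
#' Adaptive integration (lsoda) with dense output at the requested sampling
#' interval.
#'
#' @param model A [rate_model()].
#' @param state0 Initial state (length 2n, finite).
#' @param duration Integration time.
#' @param dt Output sampling interval (default 0.02).
#' @param rtol,atol Integration tolerances.
#' @return Object of class `rate_trajectory`: `time`, `state` (rows = times,
#'   columns `node<j>_E`, `node<j>_H`), `model`.
#' @export
integrate_model <- function(model, state0, duration, dt = 0.02,
                            rtol = 1e-10, atol = 1e-10) {
  if (!all(is.finite(state0))) abort("initial state must be finite")
  if (length(state0) != model$state_dim) {
    abort("initial state has the wrong length")
  }
  times <- seq(0, duration, by = dt)
  f <- function(t, y, parms) list(model_rhs(model, y))
  out <- deSolve::ode(y = state0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(out) < length(times)) {
    abort(paste0("integration failed at t = ", max(out[, 1])))
  }
  state <- unname(out[, -1, drop = FALSE])
  colnames(state) <- c(paste0("node", seq_len(model$n), "_E"),
                       paste0("node", seq_len(model$n), "_H"))
  structure(list(time = times, state = state, model = model),
            class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat("<rate_trajectory> ", length(x$time), " samples over [0, ",
      max(x$time), "], ", ncol(x$state), " state variables\n", sep = "")
  invisible(x)
}

#' @export
tidy.rate_trajectory <- function(x, ...) {
  bind_cols(tibble(time = x$time), as_tibble(x$state))
}

#' @export
autoplot.rate_trajectory <- function(object, nodes = NULL, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(-"time", names_to = "variable",
                        values_to = "value") |>
    filter(grepl("_E$", .data$variable))
  if (!is.null(nodes)) {
    df <- df |> filter(.data$variable %in% paste0("node", nodes, "_E"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "activity")
}

# drop the transient part of a trajectory
.attractor_window <- function(traj, transient = 0.6) {
  keep_from <- which(traj$time >= transient * max(traj$time))[1]
  list(time = traj$time[keep_from:length(traj$time)],
       state = traj$state[keep_from:nrow(traj$state), , drop = FALSE])
}

#' Estimate the period of an (approximately) periodic trajectory
#'
#' Autocorrelation of the first principal coordinate with parabolic peak
#' refinement.
#'
#' @param traj A `rate_trajectory`.
#' @param transient Fraction of the trajectory to discard (default 0.6).
#' @return Estimated period, or `NA` when no oscillation is detected.
#' @export
estimate_period <- function(traj, transient = 0.6) {
  w <- .attractor_window(traj, transient)
  if (max(apply(w$state, 2, function(col) diff(range(col)))) < 1e-6) {
    return(NA_real_)
  }
  z <- stats::prcomp(w$state, center = TRUE, scale. = FALSE)$x[, 1]
  if (stats::sd(z) < 1e-8) return(NA_real_)
  dt <- w$time[2] - w$time[1]
  a <- stats::acf(z, lag.max = min(length(z) - 2L, floor(length(z) / 2)),
                  plot = FALSE)$acf[, 1, 1]
  # first local max after the autocorrelation first dips below zero
  below <- which(a < 0)
  if (length(below) == 0L) return(NA_real_)
  i0 <- below[1]
  seg <- a[i0:length(a)]
  peaks <- which(diff(sign(diff(seg))) == -2) + 1L
  if (length(peaks) == 0L) return(NA_real_)
  k <- i0 + peaks[1] - 1L
  if (a[k] < 0.2) return(NA_real_)
  # parabolic refinement around the peak
  shift <- 0
  if (k > 1L && k < length(a)) {
    denom <- a[k - 1] - 2 * a[k] + a[k + 1]
    if (abs(denom) > 1e-12) shift <- 0.5 * (a[k - 1] - a[k + 1]) / denom
  }
  (k - 1 + shift) * dt
}

#' Spatiotemporal symmetry of a periodic trajectory
#'
#' For each group element, finds the phase shift minimizing the discrepancy
#' between the permuted trajectory and the time-shifted trajectory on a
#' phase-averaged cycle, and reports the (element, shift) pairs: elements
#' with small residual form the spatiotemporal symmetry group of the orbit.
#'
#' @param traj A `rate_trajectory` on an attractor.
#' @param group The `symmetry_group`.
#' @param period Period; estimated when `NULL`.
#' @param transient Fraction discarded as transient.
#' @param n_phase Phase grid resolution (default 120).
#' @return Object of class `spatiotemporal_symmetry`: tibble with `element`,
#'   `theta`, `residual` (relative), plus `period`; `periodic = FALSE` when
#'   no period is found.
#' @export
classify_spatiotemporal <- function(traj, group, period = NULL,
                                    transient = 0.6, n_phase = 120L) {
  if (is.null(period)) period <- estimate_period(traj, transient)
  if (is.na(period)) {
    return(structure(list(periodic = FALSE, period = NA_real_,
                          table = tibble()),
                     class = "spatiotemporal_symmetry"))
  }
  w <- .attractor_window(traj, transient)
  t0 <- w$time[1]
  ncyc <- max(1L, floor((max(w$time) - t0) / period) - 1L)
  phases <- (seq_len(n_phase) - 1L) / n_phase
  # phase-average the cycle to suppress residual transients
  Xbar <- matrix(0, ncol(w$state), n_phase)
  for (j in seq_len(ncol(w$state))) {
    for (pi_ in seq_len(n_phase)) {
      ts <- t0 + (seq_len(ncyc) - 1L + phases[pi_]) * period
      Xbar[j, pi_] <- mean(stats::approx(w$time, w$state[, j], xout = ts)$y)
    }
  }
  amp <- max(apply(Xbar, 1, function(r) diff(range(r))))
  if (amp < 1e-9) amp <- 1
  rows <- map(group$elements, function(p) {
    sp <- state_perm(p)
    gX <- Xbar
    gX[sp, ] <- Xbar
    resids <- map_dbl(seq_len(n_phase) - 1L, function(s) {
      idx <- ((seq_len(n_phase) - 1L + s) %% n_phase) + 1L
      sqrt(mean((gX - Xbar[, idx])^2))
    })
    k <- which.min(resids)
    # local parabolic refinement of the optimal phase
    km <- ((k - 2L) %% n_phase) + 1L
    kp <- (k %% n_phase) + 1L
    denom <- resids[km] - 2 * resids[k] + resids[kp]
    shift <- if (abs(denom) > 1e-14) {
      0.5 * (resids[km] - resids[kp]) / denom
    } else 0
    tibble(element = perm_cycles(p),
           theta = (((k - 1 + shift) / n_phase) %% 1),
           residual = resids[k] / amp)
  })
  structure(list(periodic = TRUE, period = period, table = bind_rows(rows)),
            class = "spatiotemporal_symmetry")
}

#' @export
print.spatiotemporal_symmetry <- function(x, ...) {
  if (!x$periodic) {
    cat("<spatiotemporal_symmetry> non-periodic trajectory\n")
    return(invisible(x))
  }
  cat("<spatiotemporal_symmetry> period ", format(x$period), "\n", sep = "")
  print(x$table, n = Inf)
  invisible(x)
}

#' @export
tidy.spatiotemporal_symmetry <- function(x, ...) x$table

#' Dominance trace of a trajectory
#'
#' Per sample and per attribute column, the level with uniquely maximal
#' activity (ties within tolerance are fused), compressed to the sequence of
#' distinct percepts.
#'
#' @param traj A `rate_trajectory`.
#' @param network The [rivalry_network()].
#' @param transient Fraction discarded as transient (default 0.6).
#' @param tie_tol Dominance tie tolerance (default 1e-6).
#' @param period Optional oscillation period; when given, only the last full
#'   period is classified, so the result is one cycle of the alternation.
#' @return A `percept_sequence`.
#' @export
dominance_trace <- function(traj, network, transient = 0.6, tie_tol = 1e-6,
                            period = NULL) {
  w <- .attractor_window(traj, transient)
  if (!is.null(period) && is.finite(period)) {
    keep <- w$time > max(w$time) - period
    w <- list(time = w$time[keep], state = w$state[keep, , drop = FALSE])
  }
  E <- t(w$state[, seq_len(network$n_nodes), drop = FALSE])
  per_col <- .percept_keys(E, network, tie_tol)
  new_percept_sequence(.compress_percepts(per_col, w$time))
}

#' Export a trajectory as TSV
#' @param traj A `rate_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  utils::write.table(tidy(traj), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
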