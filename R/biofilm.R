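#' Haldane (substrate-inhibited) volumetric degradation rate
#'
#' Consumption magnitude `v_max * c * rho_bio / (k_s + c + c^2/k_i)` in
#' g substrate per m^3 of biofilm per hour. The rate peaks at
#' `c = sqrt(k_s * k_i)` and declines at higher concentrations — the
#' substrate-inhibition feature that makes multiple biofilm steady states
#' possible. The sign convention is positive (a magnitude); the minus sign
#' of the consumption term is applied in the balances that use it.
#'
#' @param c Substrate concentration(s) in the biofilm (g/m^3), >= 0.
#' @param kinetics Kinetics list from a `bf_params` object (`v_max`, `k_s`,
#'   `k_i`, `rho_bio`).
#' @return Volumetric rate(s), g/m^3/h.
#' @examples
#' p <- bf_preset("steady_increase")
#' haldane_rate(sqrt(p$kinetics$k_s * p$kinetics$k_i), p$kinetics)  # the maximum
#' @export
haldane_rate <- function(c, kinetics) {
  if (any(c < 0)) stop("concentration must be >= 0", call. = FALSE)
  kinetics$v_max * c * kinetics$rho_bio /
    (kinetics$k_s + c + c^2 / kinetics$k_i)
}

# Dimensionless Haldane factor c/(k_s + c + c^2/k_i) as the discretized
# model evaluates it. The numerator keeps its sign (a small negative
# excursion of the spectral profile yields a restoring, sign-correct rate,
# so excursions stay at the 1e-3 g/m3 level and the scheme remains
# discretely conservative); the denominator's linear term is smoothed,
# |c| -> sqrt(c^2 + eps^2), which removes the pole the raw formula has at
# negative concentrations while agreeing with it to O((eps/k_s)^2) at
# physical ones. eps = 1e-4 g/m3: relative error < 1e-6 for c >= 0.01 and
# the function is smooth through zero, keeping the stiff solver's Jacobian
# well behaved.
.haldane_factor <- function(c, k_s, k_i, eps = 1e-4) {
  c / (k_s + sqrt(c * c + eps * eps) + c * c / k_i)
}

#' Depth-averaged biofilm reaction rate
#'
#' Quadrature of the Haldane rate over the dimensionless biofilm depth
#' x' in \[0, 1\]: the mean volumetric consumption rate that enters the
#' gas-phase balance as `rho_bulk * A * L * rbar`.
#'
#' @param c_profile Concentrations at the biofilm nodes (g/m^3), substratum
#'   (x' = 0) first, gas interface (x' = 1) last.
#' @param kinetics Kinetics list from a `bf_params` object.
#' @param grid The biofilm [colloc_grid()] (same length as `c_profile`).
#' @return Mean volumetric rate, g/m^3/h.
#' @export
average_rate <- function(c_profile, kinetics, grid) {
  integrate_profile(grid, haldane_rate(pmax(c_profile, 0), kinetics))
}

# Given the free film values (substratum implied) and the pinned surface
# value, reconstruct the full node profile. u holds interior nodes only
# (rows 2..n-1); the substratum value follows from the zero-flux condition
# applied through the first row of d1, the surface value from Henry's law.
.film_full_profile <- function(u, c_surf, grid) {
  n <- grid$n
  d1row <- grid$d1[1, ]
  c1 <- -(sum(d1row[2:(n - 1)] * u) + d1row[n] * c_surf) / d1row[1]
  c(c1, u, c_surf)
}

#' Time derivative of the biofilm concentration profile
#'
#' Method-of-lines right-hand side of the planar reaction-diffusion
#' equation `dC/dt = (D/L^2) d2C/dx'^2 - r(C)` with the surface node pinned
#' to `c_gas / H` (Henry's law) and zero flux at the substratum. The surface
#' slot of the returned vector is 0 (it is not a free state); the substratum
#' slot carries the derivative implied by differentiating the zero-flux
#' constraint in time, so a consistent profile stays consistent.
#'
#' @param state List with `c_profile` (full node profile, g/m^3) and
#'   `thickness_l` (biofilm thickness L, m, > 0).
#' @param c_gas Local gas-phase concentration (g/m^3).
#' @param params A `bf_params` object.
#' @param grid The biofilm [colloc_grid()]; defaults to the grid implied by
#'   `params$discretization$n_biofilm`.
#' @return Vector of node time-derivatives (g/m^3/h).
#' @export
biofilm_rhs <- function(state, c_gas, params, grid = NULL) {
  if (is.null(grid)) grid <- colloc_grid(params$discretization$n_biofilm - 2L)
  L <- state$thickness_l
  if (!is.numeric(L) || L <= 0) {
    stop("degenerate biofilm: thickness must be > 0 (callers bypass the film ",
         "when L underflows)", call. = FALSE)
  }
  cp <- state$c_profile
  n <- grid$n
  stopifnot(length(cp) == n)
  k <- params$kinetics
  Dh <- params$transport$diffusivity_d
  diff_term <- (Dh / L^2) * as.numeric(grid$d2 %*% cp)
  reac <- k$v_max * k$rho_bio * .haldane_factor(cp, k$k_s, k$k_i)
  dc <- diff_term - reac
  dc[n] <- 0  # surface pinned to c_gas/H
  # substratum: time-differentiated zero-flux constraint
  d1row <- grid$d1[1, ]
  dc[1] <- -sum(d1row[2:n] * dc[2:n]) / d1row[1]
  dc
}

#' Steady-state biofilm profile (boundary-value solve)
#'
#' Solves the steady reaction-diffusion balance `(D/L^2) C'' = r(C)` with
#' `C(1) = c_gas / H` and `C'(0) = 0` by damped Newton iteration on the
#' collocation residual. When the film is thick enough for substrate
#' inhibition to matter, several roots coexist; the converged root then
#' depends on `init` (see `init_kind`).
#'
#' @param c_gas Gas-phase concentration at the interface (g/m^3), >= 0.
#' @param thickness_l Biofilm thickness L (m), > 0.
#' @param params A `bf_params` object.
#' @param grid Optional biofilm [colloc_grid()]; defaults to the grid implied
#'   by `params$discretization$n_biofilm`.
#' @param init Optional full-length initial node profile. Overrides
#'   `init_kind`.
#' @param init_kind Either `"depleted"` (first-order diffusion-limited shape,
#'   converging to the high-activity branch where it exists) or
#'   `"saturated"` (uniform profile at `c_gas / H`, converging to the
#'   low-activity branch).
#' @param tol Convergence tolerance on the scaled residual norm.
#' @param max_iter Newton iteration cap.
#' @return A list of class `bf_film_state`: `c_profile`, `thickness_l`,
#'   `flux` (interface flux `D/L * dC/dx'` at x' = 1, g/m^2/h), `converged`,
#'   `residual_norm`, `iterations`.
#' @export
solve_biofilm_steady <- function(c_gas, thickness_l, params, grid = NULL,
                                 init = NULL, init_kind = c("depleted", "saturated"),
                                 tol = 1e-10, max_iter = 60L) {
  init_kind <- match.arg(init_kind)
  if (c_gas < 0) stop("`c_gas` must be >= 0", call. = FALSE)
  if (thickness_l <= 0) stop("`thickness_l` must be > 0", call. = FALSE)
  if (is.null(grid)) grid <- colloc_grid(params$discretization$n_biofilm - 2L)
  n <- grid$n
  k <- params$kinetics
  Dh <- params$transport$diffusivity_d
  c_surf <- c_gas / params$transport$henry_h
  L <- thickness_l

  if (is.null(init)) {
    init <- switch(init_kind,
      saturated = rep(c_surf, n),
      depleted = {
        # first-order (low-concentration) closed form as a depleted-shape seed
        phi <- L * sqrt(k$v_max * k$rho_bio / (k$k_s * Dh))
        prof <- c_surf * cosh(pmin(phi, 350) * grid$nodes) / cosh(pmin(phi, 350))
        prof[!is.finite(prof)] <- 0
        prof
      }
    )
  }
  stopifnot(length(init) == n)

  free <- 2:(n - 1)
  u <- init[free]
  scale <- max(c_surf, k$k_s)   # concentration scale for the residual norm

  residual <- function(u) {
    cp <- .film_full_profile(u, c_surf, grid)
    res <- (Dh / L^2) * as.numeric(grid$d2 %*% cp) -
      k$v_max * k$rho_bio * .haldane_factor(cp, k$k_s, k$k_i)
    res[free] / (Dh / L^2)   # scaled to concentration units
  }

  newton <- function(u) {
    r <- residual(u)
    rn <- sqrt(mean(r^2))
    it <- 0L
    m <- length(u)
    while (rn > tol * scale && it < max_iter) {
      it <- it + 1L
      # finite-difference Jacobian (small dense system)
      J <- matrix(0, m, m)
      h <- pmax(abs(u), scale * 1e-3) * 1e-7
      for (j in seq_len(m)) {
        up <- u; up[j] <- up[j] + h[j]
        J[, j] <- (residual(up) - r) / h[j]
      }
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        u_new <- u + lambda * step
        r_new <- residual(u_new)
        rn_new <- sqrt(mean(r_new^2))
        if (rn_new < rn || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      u <- u_new; r <- r_new; rn <- rn_new
    }
    list(u = u, rn = rn, it = it, converged = rn <= tol * scale)
  }

  sol <- newton(u)
  if (!sol$converged) {
    # pseudo-transient continuation: relax the film ODE from the seed toward
    # the stable steady state in its basin, then polish with Newton. Robust
    # when the seed is far from any root (e.g. a saturated seed below the
    # lower fold, where only the depleted state exists).
    rhs <- function(t, uu, p) {
      cp <- .film_full_profile(uu, c_surf, grid)
      dc <- (Dh / L^2) * as.numeric(grid$d2 %*% cp) -
        k$v_max * k$rho_bio * .haldane_factor(cp, k$k_s, k$k_i)
      list(dc[free])
    }
    tau <- L^2 / Dh
    uu <- u
    for (chunk in 1:8) {
      out <- tryCatch(
        deSolve::ode(y = uu, times = c(0, 500 * tau), func = rhs, parms = NULL,
                     method = "lsoda", rtol = 1e-9, atol = 1e-11 * max(c_surf, 1)),
        error = function(e) NULL)
      if (is.null(out) || nrow(out) < 2) break
      uu <- as.numeric(out[nrow(out), -1])
      cand <- newton(uu)
      if (cand$converged) { sol <- cand; break }
    }
  }
  u <- sol$u
  rn <- sol$rn
  it <- sol$it
  converged <- sol$converged
  cp <- .film_full_profile(u, c_surf, grid)
  flux <- (Dh / L) * sum(grid$d1[n, ] * cp)
  structure(
    list(c_profile = cp, thickness_l = L, flux = flux,
         converged = converged, residual_norm = rn, iterations = it),
    class = "bf_film_state"
  )
}

# are two converged profiles the same root?
.same_profile <- function(a, b, scale) {
  max(abs(a - b)) <= 1e-4 * max(scale, 1e-12)
}

#' Steady-state multiplicity scan over gas concentration
#'
#' Sweeps the gas-phase concentration upward with high-activity continuation
#' (each solve seeded from the previous high-activity profile) and downward
#' with low-activity continuation, collecting every distinct steady biofilm
#' state found at each concentration. Where the two continuations disagree,
#' the film is bistable; the scan reports the hysteresis window and refines
#' its fold (turning-point) concentrations by bisection.
#'
#' @param c_gas_range Increasing vector of gas concentrations (g/m^3).
#' @param thickness_l Biofilm thickness L (m).
#' @param params A `bf_params` object.
#' @param grid Optional biofilm [colloc_grid()].
#' @param refine_folds Bisection refinement of the window edges (default TRUE).
#' @param label_stability If TRUE, verify each branch by short time
#'   integration from a 1 percent perturbation (slower; default FALSE —
#'   branches found by the two continuations are the stable outer branches).
#' @return A list of class `bf_scan`: `branches` (data.frame with columns
#'   `c_gas`, `flux`, `branch_label`, `surface_concentration`), `window`
#'   (c(lower, upper) fold concentrations, or NULL when the scan finds a
#'   unique state everywhere), `profiles` (list of node profiles).
#' @export
multiplicity_scan <- function(c_gas_range, thickness_l, params, grid = NULL,
                              refine_folds = TRUE, label_stability = FALSE) {
  stopifnot(length(c_gas_range) >= 1, !is.unsorted(c_gas_range, strictly = TRUE))
  if (is.null(grid)) grid <- colloc_grid(params$discretization$n_biofilm - 2L)
  H <- params$transport$henry_h

  solve_at <- function(cg, init, kind) {
    solve_biofilm_steady(cg, thickness_l, params, grid, init = init,
                         init_kind = kind)
  }

  nscan <- length(c_gas_range)
  up <- vector("list", nscan)     # high-activity continuation, sweeping up
  prev <- NULL
  for (i in seq_len(nscan)) {
    s <- solve_at(c_gas_range[i], prev, "depleted")
    if (!s$converged) s <- solve_at(c_gas_range[i], NULL, "depleted")
    up[[i]] <- s
    prev <- if (s$converged) s$c_profile else NULL
  }
  down <- vector("list", nscan)   # low-activity continuation, sweeping down
  prev <- NULL
  for (i in rev(seq_len(nscan))) {
    s <- solve_at(c_gas_range[i], prev, "saturated")
    if (!s$converged) s <- solve_at(c_gas_range[i], NULL, "saturated")
    down[[i]] <- s
    prev <- if (s$converged) s$c_profile else NULL
  }

  rows <- list(); profiles <- list()
  two_state <- logical(nscan)
  for (i in seq_len(nscan)) {
    cg <- c_gas_range[i]
    cs <- cg / H
    a <- up[[i]]; b <- down[[i]]
    ok_a <- a$converged; ok_b <- b$converged
    distinct <- ok_a && ok_b && !.same_profile(a$c_profile, b$c_profile, cs)
    two_state[i] <- distinct
    if (distinct) {
      hi <- if (a$flux >= b$flux) a else b
      lo <- if (a$flux >= b$flux) b else a
      rows[[length(rows) + 1L]] <- data.frame(
        c_gas = cg, flux = hi$flux, branch_label = "high_activity",
        surface_concentration = cs)
      profiles[[length(profiles) + 1L]] <- hi$c_profile
      rows[[length(rows) + 1L]] <- data.frame(
        c_gas = cg, flux = lo$flux, branch_label = "low_activity",
        surface_concentration = cs)
      profiles[[length(profiles) + 1L]] <- lo$c_profile
    } else if (ok_a || ok_b) {
      s <- if (ok_a) a else b
      rows[[length(rows) + 1L]] <- data.frame(
        c_gas = cg, flux = s$flux, branch_label = "unique",
        surface_concentration = cs)
      profiles[[length(profiles) + 1L]] <- s$c_profile
    }
  }
  branches <- do.call(rbind, rows)

  window <- NULL
  if (any(two_state)) {
    lo_idx <- which(two_state)[1]
    hi_idx <- which(two_state)[sum(two_state)]
    lower <- c_gas_range[lo_idx]
    upper <- c_gas_range[hi_idx]
    if (refine_folds) {
      two_here <- function(cg) {
        a <- solve_at(cg, NULL, "depleted")
        b <- solve_at(cg, NULL, "saturated")
        a$converged && b$converged &&
          !.same_profile(a$c_profile, b$c_profile, cg / H)
      }
      if (lo_idx > 1) {
        lo0 <- c_gas_range[lo_idx - 1]; hi0 <- lower
        for (it in 1:25) {
          mid <- (lo0 + hi0) / 2
          if (two_here(mid)) hi0 <- mid else lo0 <- mid
        }
        lower <- hi0
      }
      if (hi_idx < nscan) {
        lo0 <- upper; hi0 <- c_gas_range[hi_idx + 1]
        for (it in 1:25) {
          mid <- (lo0 + hi0) / 2
          if (two_here(mid)) lo0 <- mid else hi0 <- mid
        }
        upper <- lo0
      }
    }
    window <- c(lower = lower, upper = upper)
  }

  if (label_stability && !is.null(branches)) {
    for (i in seq_len(nrow(branches))) {
      if (branches$branch_label[i] == "unique") next
      stable <- .film_branch_stable(profiles[[i]], branches$c_gas[i],
                                    thickness_l, params, grid)
      if (!stable) branches$branch_label[i] <- "intermediate"
    }
  }

  structure(list(branches = branches, window = window, profiles = profiles,
                 thickness_l = thickness_l),
            class = "bf_scan")
}

# short time-integration from a 1% perturbation; returns TRUE if the state
# is recovered (stable branch)
.film_branch_stable <- function(profile, c_gas, thickness_l, params, grid) {
  n <- grid$n
  free <- 2:(n - 1)
  c_surf <- c_gas / params$transport$henry_h
  k <- params$kinetics
  Dh <- params$transport$diffusivity_d
  tau <- thickness_l^2 / Dh   # diffusion time scale
  rhs <- function(t, u, p) {
    cp <- .film_full_profile(u, c_surf, grid)
    dc <- (Dh / thickness_l^2) * as.numeric(grid$d2 %*% cp) -
      k$v_max * k$rho_bio * .haldane_factor(cp, k$k_s, k$k_i)
    list(dc[free])
  }
  u0 <- profile[free] * 1.01
  out <- deSolve::ode(y = u0, times = c(0, 50 * tau), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  uT <- out[nrow(out), -1]
  max(abs(uT - profile[free])) < 0.05 * max(c_surf, 1e-9)
}

#' Write a biofilm profile or multiplicity scan to delimited text
#'
#' Profiles go out as `x_prime, c_biofilm`; scans as
#' `c_gas, flux, branch_label`.
#'
#' @param x A `bf_film_state` or `bf_scan` object.
#' @param path Output CSV path.
#' @param grid The biofilm grid used (needed for profile node positions).
#' @return `path`, invisibly.
#' @export
write_biofilm_csv <- function(x, path, grid = NULL) {
  if (inherits(x, "bf_film_state")) {
    if (is.null(grid)) stop("`grid` is required to write a profile", call. = FALSE)
    utils::write.csv(data.frame(x_prime = grid$nodes, c_biofilm = x$c_profile),
                     path, row.names = FALSE)
  } else if (inherits(x, "bf_scan")) {
    utils::write.csv(x$branches[, c("c_gas", "flux", "branch_label")],
                     path, row.names = FALSE)
  } else {
    stop("unsupported object", call. = FALSE)
  }
  invisible(path)
}
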