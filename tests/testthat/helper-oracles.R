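# Independent numerical oracles and shared (memoized) fixtures.

# ---- dense finite-difference steady biofilm solver --------------------------
# Second-order central differences on a uniform grid, Neumann condition at the
# substratum via a symmetric ghost node, Dirichlet (c_gas/H) at the surface.
# Damped Newton with an analytic tridiagonal Jacobian (Thomas solve); if a
# cold seed fails to converge, the film ODE is relaxed toward the stable
# state (banded method of lines) and Newton is re-applied.
# Independent of the package's collocation path.
fd_film_steady <- function(c_gas, thickness_l, params, n = 500,
                           init = c("depleted", "saturated"), maxit = 120) {
  init <- match.arg(init)
  k <- params$kinetics
  Dh <- params$transport$diffusivity_d
  cs <- c_gas / params$transport$henry_h
  h <- 1 / (n - 1)
  x <- seq(0, 1, length.out = n)
  DL2 <- Dh / thickness_l^2
  scale <- DL2 / h^2

  rate <- function(c) {
    cp <- pmax(c, 0)
    k$v_max * k$rho_bio * cp / (k$k_s + cp + cp^2 / k$k_i)
  }
  rate_d <- function(c) {
    cp <- pmax(c, 0)
    den <- k$k_s + cp + cp^2 / k$k_i
    ifelse(c > 0,
           k$v_max * k$rho_bio * (k$k_s - cp^2 / k$k_i) / den^2,
           k$v_max * k$rho_bio / k$k_s)
  }
  resid <- function(u) {
    r <- numeric(n - 1)
    r[1] <- DL2 * 2 * (u[2] - u[1]) / h^2 - rate(u[1])
    i <- 2:(n - 1)
    r[i] <- DL2 * (u[i - 1] - 2 * u[i] + u[i + 1]) / h^2 - rate(u[i])
    r
  }
  tol_ok <- function(r) max(abs(r)) < 1e-9 * scale * max(cs, 1e-3)

  newton <- function(u) {
    r <- resid(u)
    for (it in seq_len(maxit)) {
      if (tol_ok(r)) break
      nn <- n - 1
      sub <- rep(DL2 / h^2, nn)
      dia <- c(-2 * DL2 / h^2 - rate_d(u[1]),
               -2 * DL2 / h^2 - rate_d(u[2:(n - 1)]))
      sup <- c(2 * DL2 / h^2, rep(DL2 / h^2, nn - 1))
      cp_ <- numeric(nn); dp_ <- numeric(nn)
      cp_[1] <- sup[1] / dia[1]; dp_[1] <- -r[1] / dia[1]
      for (j in 2:nn) {
        m <- dia[j] - sub[j] * cp_[j - 1]
        cp_[j] <- if (j < nn) sup[j] / m else 0
        dp_[j] <- (-r[j] - sub[j] * dp_[j - 1]) / m
      }
      du <- numeric(nn); du[nn] <- dp_[nn]
      for (j in (nn - 1):1) du[j] <- dp_[j] - cp_[j] * du[j + 1]
      lam <- 1
      repeat {
        un <- u; un[1:nn] <- u[1:nn] + lam * du
        rn <- resid(un)
        if (max(abs(rn)) < max(abs(r)) || lam < 1e-4) break
        lam <- lam / 2
      }
      u <- un; r <- rn
    }
    list(u = u, converged = tol_ok(r))
  }

  phi <- thickness_l * sqrt(k$v_max * k$rho_bio / (k$k_s * Dh))
  u <- if (init == "saturated") rep(cs, n) else cs * exp(pmin(0, phi * (x - 1)))
  u[n] <- cs

  sol <- newton(u)
  if (!sol$converged) {
    rhs <- function(t, uu, p) list(resid(c(uu, cs)))
    tau <- thickness_l^2 / Dh
    uu <- u[1:(n - 1)]
    for (chunk in 1:8) {
      out <- tryCatch(
        deSolve::ode(y = uu, times = c(0, 500 * tau), func = rhs, parms = NULL,
                     method = "lsoda", jactype = "bandint", bandup = 1,
                     banddown = 1, rtol = 1e-8, atol = 1e-10 * max(cs, 1)),
        error = function(e) NULL)
      if (is.null(out) || nrow(out) < 2) break
      uu <- as.numeric(out[nrow(out), -1])
      cand <- newton(c(uu, cs))
      if (cand$converged) { sol <- cand; break }
    }
  }
  u <- sol$u
  flux <- Dh / thickness_l * (3 * u[n] - 4 * u[n - 1] + u[n - 2]) / (2 * h)
  list(profile = u, x = x, flux = flux, converged = sol$converged)
}

# all distinct steady states a solver finds from both cold seeds
film_states_multistart <- function(solver, c_gas, ...) {
  sols <- list()
  for (seed in c("depleted", "saturated")) {
    s <- solver(c_gas, seed)
    if (isTRUE(s$converged)) sols[[length(sols) + 1L]] <- s
  }
  if (length(sols) == 2 &&
      abs(sols[[1]]$flux - sols[[2]]$flux) <
        1e-3 * max(abs(sols[[1]]$flux), 1e-12)) {
    sols <- sols[1]
  }
  sols[order(vapply(sols, function(s) s$flux, numeric(1)))]
}

# ---- memoized expensive fixtures -------------------------------------------
.fixture_cache <- new.env(parent = emptyenv())

# the headline 40-day steadily-ramped simulation (shared by several tests)
ramp_fixture <- function() {
  if (is.null(.fixture_cache$ramp)) {
    .fixture_cache$ramp <- run_ramp_scenario(ramp_scenario_params(),
                                             increment = 0.272, n_days = 40)
  }
  .fixture_cache$ramp
}
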