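kin <- bf_preset("steady_increase")$kinetics

test_that("Haldane rate matches closed-form values and rejects bad input", {
  expect_equal(haldane_rate(0, kin), 0)
  expect_error(haldane_rate(-0.1, kin), ">= 0")

  # global maximum at sqrt(k_s * k_i)
  cstar <- sqrt(kin$k_s * kin$k_i)
  expect_equal(cstar, 0.3674235, tolerance = 1e-6)
  rmax <- kin$v_max * cstar * kin$rho_bio /
    (kin$k_s + cstar + cstar^2 / kin$k_i)
  expect_equal(haldane_rate(cstar, kin), rmax)
  expect_equal(rmax, 2.35818e4, tolerance = 1e-5)
  expect_equal(haldane_rate(kin$k_s, kin), 1.48624e4, tolerance = 1e-5)
})

test_that("Haldane rate rises to sqrt(k_s k_i) and falls beyond it", {
  set.seed(42)
  cstar <- sqrt(kin$k_s * kin$k_i)
  lo <- sort(runif(50, 0, cstar))
  hi <- sort(runif(50, cstar, 20))
  expect_true(all(diff(haldane_rate(lo, kin)) > 0))
  expect_true(all(diff(haldane_rate(hi, kin)) < 0))
  expect_true(all(haldane_rate(hi, kin) < haldane_rate(cstar, kin)))
})

test_that("biofilm RHS honours the boundary conditions", {
  p <- bf_preset("steady_increase")
  g <- colloc_grid(p$discretization$n_biofilm - 2L)
  c_gas <- 2.5
  # surface value constrained through Henry's law: 2.5 / 0.25 = 10
  s <- solve_biofilm_steady(c_gas, 1e-5, p)
  expect_equal(s$c_profile[g$n], 10)

  # no reaction + uniform profile at c_gas/H: nothing moves
  p0 <- p; p0$kinetics$v_max <- 1e-300
  st <- list(c_profile = rep(c_gas / 0.25, g$n), thickness_l = 1e-5)
  dc <- biofilm_rhs(st, c_gas, p0, g)
  expect_lt(max(abs(dc)), 1e-6)

  expect_error(biofilm_rhs(list(c_profile = rep(1, g$n), thickness_l = 0),
                           c_gas, p, g), "degenerate")

  # a converged steady profile is a fixed point of the dynamics
  dc <- biofilm_rhs(list(c_profile = s$c_profile, thickness_l = 1e-5),
                    c_gas, p, g)
  expect_lt(max(abs(dc[2:(g$n - 1)])), 1e-4 * max(s$c_profile))
})

test_that("steady solutions match analytic limits", {
  p <- bf_preset("steady_increase")
  g <- colloc_grid(8)
  # pure diffusion (no sink): uniform profile at c_gas/H
  p0 <- p; p0$kinetics$v_max <- 1e-300
  s <- solve_biofilm_steady(3.2, 1e-5, p0, g)
  expect_true(s$converged)
  expect_equal(s$c_profile, rep(3.2 / 0.25, g$n), tolerance = 1e-8)

  # first-order regime: classical cosh profile
  L <- 1e-6
  cg <- 1e-4
  s <- solve_biofilm_steady(cg, L, p, g)
  k1 <- p$kinetics$v_max * p$kinetics$rho_bio / p$kinetics$k_s
  phi <- L * sqrt(k1 / p$transport$diffusivity_d)
  exact <- (cg / p$transport$henry_h) * cosh(phi * g$nodes) / cosh(phi)
  expect_lt(max(abs(s$c_profile - exact)) / max(exact), 0.01)
  expect_equal(s$flux,
               (p$transport$diffusivity_d / L) * (cg / 0.25) * phi * tanh(phi),
               tolerance = 0.01)
})

test_that("steady profiles are monotone and flux balances consumption", {
  p <- bf_preset("two_steady_states")
  g <- colloc_grid(18)   # well-resolved film for the quantitative balance
  for (cg in c(0.5, 2, 6)) {
    s <- solve_biofilm_steady(cg, 2e-5, p, g)
    expect_true(s$converged)
    # monotone up to the small oscillation of the spectral boundary layer
    expect_true(all(diff(s$c_profile) > -0.01 * max(s$c_profile)))
    rbar <- average_rate(s$c_profile, p$kinetics, g)
    expect_equal(s$flux, s$thickness_l * rbar,
                 tolerance = 5e-3)
  }
})

test_that("depth-averaged rate agrees with a dense quadrature oracle", {
  g <- colloc_grid(8)
  # constant integrand: quadrature is exact
  expect_equal(average_rate(rep(0.2, g$n), kin, g), haldane_rate(0.2, kin))
  expect_equal(average_rate(rep(0, g$n), kin, g), 0)
  # linear profile 0 -> 0.1 vs brute-force trapezoid at 1e4 points
  prof <- 0.1 * g$nodes
  xs <- seq(0, 1, length.out = 1e4)
  dense <- mean(haldane_rate(0.1 * xs, kin)[-1] + haldane_rate(0.1 * xs, kin)[-1e4]) / 2
  expect_equal(average_rate(prof, kin, g), dense, tolerance = 5e-3)
})

test_that("multiplicity scan finds the bistable window of a thick film", {
  p <- bf_preset("two_steady_states")
  sc <- multiplicity_scan(seq(3, 12, by = 0.5), 5.5e-5, p)
  expect_false(is.null(sc$window))
  # hysteresis window overlaps the concentration range where the observed
  # high-to-low transition occurred (7.7 - 8.5 g/m3)
  expect_lt(sc$window["lower"], 8.5)
  expect_gt(sc$window["upper"], 7.7)
  # both branches reported inside the window, high flux above low flux
  br <- sc$branches
  for (cgv in unique(br$c_gas[br$branch_label == "high_activity"])) {
    hi <- br$flux[br$c_gas == cgv & br$branch_label == "high_activity"]
    lo <- br$flux[br$c_gas == cgv & br$branch_label == "low_activity"]
    expect_gt(hi, lo)
  }
})

test_that("thin films have a unique steady state", {
  p <- bf_preset("two_steady_states")
  sc <- multiplicity_scan(seq(1, 12, by = 1), 1e-7, p)
  expect_null(sc$window)
  expect_true(all(sc$branches$branch_label == "unique"))
})
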