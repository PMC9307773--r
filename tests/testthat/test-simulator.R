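test_that("specific growth combines Haldane and nitrogen Monod factors", {
  p <- bf_preset("steady_increase")
  expect_equal(specific_growth(0, 0.5, p), 0)
  # nitrogen saturation: Monod factor -> 1
  cstar <- sqrt(p$kinetics$k_s * p$kinetics$k_i)
  mu_sat <- specific_growth(cstar, 1e6, p)
  fh <- cstar / (p$kinetics$k_s + cstar + cstar^2 / p$kinetics$k_i)
  expect_equal(mu_sat, p$kinetics$mu_max * fh, tolerance = 1e-5)
  # half-saturated nitrogen at the Haldane optimum
  expect_equal(specific_growth(cstar, 0.5, p), 0.0393031, tolerance = 1e-4)
  # net rate at zero substrate is pure decay
  expect_equal(specific_growth(0, 0.5, p) - p$kinetics$decay_a, -0.0014)
})

test_that("nitrogen balance has the published abiotic equilibrium", {
  p <- bf_preset("steady_increase")
  ni <- p$nitrogen
  n_eq <- ni$k_min * ni$n_org / ni$k_uptake
  expect_equal(n_eq, 0.476636, tolerance = 1e-5)
  expect_equal(nitrogen_rhs(n_eq, 0, 1e-5, p), 0, tolerance = 1e-15)
  # all-zero state: pure mineralization
  expect_equal(nitrogen_rhs(0, 0, 0, p), 1.0486e-3, tolerance = 1e-4)
  # biomass uptake term: mu * f_n * rho_bio * A * L
  d <- nitrogen_rhs(0, 0.1, 1e-6, p) - nitrogen_rhs(0, 0, 1e-6, p)
  expect_equal(d, -0.1 * 0.126 * 1e5 * p$transport$area_a * 1e-6)
})

test_that("thickness follows the biomass/area relation", {
  p <- bf_preset("two_steady_states")   # A = 0.95
  expect_equal(thickness_from_biomass(0, p), 0)
  expect_equal(thickness_from_biomass(0.003, p), 3.1579e-8, tolerance = 1e-4)
  expect_equal(thickness_from_biomass(0.95 * 1e5 * 1e-4, p), 1e-4)
})

test_that("column with no activity passes gas through and decays biomass", {
  p <- bf_preset("steady_increase")
  p$kinetics$v_max <- 1e-300
  p$kinetics$mu_max <- 1e-300
  r <- simulate_biofilter(bf_schedule(0, 2.0), p, t_end = 48)
  tb <- r$table
  last <- tb[nrow(tb), ]
  # outlet equals inlet at steady state (no sink)
  expect_equal(last$c_out, 2.0, tolerance = 1e-3)
  # biomass decays exponentially at the decay rate
  expect_equal(last$mean_biomass, p$x0 * exp(-p$kinetics$decay_a * 48),
               tolerance = 1e-5)
  expect_equal(last$mean_thickness_m,
               thickness_from_biomass(last$mean_biomass, p), tolerance = 1e-9)
})

test_that("zero inlet yields zero outlet", {
  p <- bf_preset("steady_increase")
  r <- simulate_biofilter(bf_schedule(0, 0), p, t_end = 24)
  expect_lt(max(abs(r$table$c_out)), 1e-8)
})

test_that("sampling interval does not perturb the dynamics", {
  p <- bf_preset("steady_increase")
  r1 <- simulate_biofilter(bf_schedule(0, 1.0), p, t_end = 12, sample_every = 2)
  r2 <- simulate_biofilter(bf_schedule(0, 1.0), p, t_end = 12, sample_every = 1)
  shared <- intersect(r1$table$time_h, r2$table$time_h)
  a <- r1$table$c_out[match(shared, r1$table$time_h)]
  b <- r2$table$c_out[match(shared, r2$table$time_h)]
  expect_equal(a, b, tolerance = 1e-4)
})

test_that("first-order regime reproduces the plug-flow closed form", {
  p <- bf_preset("steady_increase")
  p$kinetics$mu_max <- 1e-300       # frozen biomass
  p$kinetics$decay_a <- 1e-300
  L <- 3e-8
  p$x0 <- L * p$transport$area_a * p$kinetics$rho_bio
  p$discretization$solver_atol <- 1e-14
  cin <- 1e-5                       # far below k_s * H: first-order kinetics
  r <- simulate_biofilter(bf_schedule(0, cin), p, t_end = 10)
  c_out <- r$table$c_out[nrow(r$table)]
  k <- p$kinetics; tr <- p$transport
  k1 <- k$v_max * k$rho_bio / k$k_s
  phi <- L * sqrt(k1 / tr$diffusivity_d)
  pred <- cin * exp(-tr$rho_bulk * tr$area_a * sqrt(k1 * tr$diffusivity_d) *
                      tanh(phi) * tr$bed_height /
                      (tr$superficial_velocity * tr$henry_h))
  expect_equal(c_out, pred, tolerance = 0.01)
})

test_that("quasi-steady outlet is insensitive to grid refinement", {
  base <- bf_preset("steady_increase")
  base$kinetics$mu_max <- 1e-300
  base$kinetics$decay_a <- 1e-300
  base$x0 <- 3e-6 * base$transport$area_a * base$kinetics$rho_bio  # L = 3 um
  run <- function(na, nb) {
    p <- base
    p$discretization$n_axial <- na
    p$discretization$n_biofilm <- nb
    r <- simulate_biofilter(bf_schedule(0, 2.0), p, t_end = 8)
    r$table$c_out[nrow(r$table)]
  }
  c_coarse <- run(25L, 10L)
  c_fine <- run(50L, 20L)
  expect_equal(c_coarse, c_fine, tolerance = 0.02)
})

test_that("snapshots expose consistent column state and film profiles", {
  p <- bf_preset("steady_increase")
  p$kinetics$v_max <- 1e-300
  r <- simulate_biofilter(bf_schedule(0, 1.6), p, t_end = 12)
  st <- state_at(r, 12)
  expect_equal(st$c_gas[1], 1.6)                      # inlet pinned
  expect_equal(length(st$c_gas), p$discretization$n_axial)
  # no reaction: films equilibrate flat at c_gas/H
  pr <- biofilm_profile_at(r, 12, 3)
  expect_equal(pr$c_biofilm,
               rep(st$c_gas[3] / 0.25, p$discretization$n_biofilm),
               tolerance = 1e-3)
  expect_equal(pr$depth_m[nrow(pr)], st$thickness_l[3])
  expect_error(biofilm_profile_at(r, 12, 99), "axial_index")
  expect_error(state_at(r, 1e5), "no snapshot")
})

test_that("a run can be continued from its final state", {
  p <- bf_preset("steady_increase")
  sched <- bf_schedule(0, 1.0)
  r1 <- simulate_biofilter(sched, p, t_end = 6)
  r2 <- simulate_biofilter(sched, p, t_end = 12, t0 = 6,
                           init = final_state(r1))
  rfull <- simulate_biofilter(sched, p, t_end = 12)
  expect_equal(r2$table$c_out[nrow(r2$table)],
               rfull$table$c_out[nrow(rfull$table)], tolerance = 1e-4)
})
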