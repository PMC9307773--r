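test_that("presets reproduce the published parameter columns", {
  si <- bf_preset("steady_increase")
  expect_equal(si$transport$area_a, 1.1)
  expect_equal(si$transport$diffusivity_d, 1.5e-11 * 3600)
  expect_equal(si$transport$rho_bulk, 555)
  expect_equal(si$kinetics$k_i, 2.7)

  tss <- bf_preset("two_steady_states")
  expect_equal(tss$transport$area_a, 0.95)
  expect_equal(tss$transport$diffusivity_d, 1.5e-10 * 3600)

  be <- bf_preset("biofilter_experiment")
  expect_equal(be$transport$rho_bulk, 306)
  expect_equal(be$transport$area_a, 0.2375)

  # shared constants identical across columns
  shared <- list(
    c("kinetics", "v_max", 0.3), c("kinetics", "k_s", 0.05),
    c("kinetics", "mu_max", 0.1), c("kinetics", "decay_a", 0.0014),
    c("kinetics", "yield_y", 0.5), c("kinetics", "rho_bio", 1e5),
    c("transport", "henry_h", 0.25), c("transport", "superficial_velocity", 3.63),
    c("transport", "porosity_eps", 0.55),
    c("nitrogen", "n_org", 14.98), c("nitrogen", "k_min", 0.00007),
    c("nitrogen", "k_uptake", 0.0022), c("nitrogen", "k_n", 0.5),
    c("nitrogen", "f_n", 0.126)
  )
  for (s in shared) {
    for (p in list(si, tss, be)) {
      expect_equal(p[[s[1]]][[s[2]]], as.numeric(s[3]))
    }
  }
  for (p in list(si, tss, be)) expect_equal(p$x0, 0.003)

  # the three columns differ only in area, diffusivity and bulk density
  strip <- function(p) {
    p$transport$area_a <- NULL
    p$transport$diffusivity_d <- NULL
    p$transport$rho_bulk <- NULL
    unclass(p)
  }
  expect_identical(strip(si), strip(tss))
  expect_identical(strip(si), strip(be))

  expect_error(bf_preset("nonexistent"), "unknown preset")
})

test_that("config loading converts units, validates and round-trips", {
  cfg <- system.file("extdata", "example_config.yaml", package = "biofiltr")
  p <- bf_load_params(cfg)
  # the example config is the bistable column: diffusivity entered in m^2/s
  expect_equal(p$transport$diffusivity_d, 1.5e-10 * 3600)
  expect_equal(p$transport$area_a, 0.95)

  f <- tempfile(fileext = ".yaml")
  bf_save_params(p, f)
  p2 <- bf_load_params(f)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)

  # invalid documents are rejected with informative errors
  doc <- yaml::read_yaml(cfg)
  bad <- doc; bad$transport$porosity_eps <- 1.2
  yaml::write_yaml(bad, f)
  expect_error(bf_load_params(f), "porosity_eps")

  bad <- doc; bad$kinetics$k_i <- 0.01   # below k_s: no Haldane maximum
  yaml::write_yaml(bad, f)
  expect_error(bf_load_params(f), "k_i")

  bad <- doc; bad$kinetics$v_max <- NULL
  yaml::write_yaml(bad, f)
  expect_error(bf_load_params(f), "v_max")

  bad <- doc; bad$kinetics$not_a_knob <- 1
  yaml::write_yaml(bad, f)
  expect_error(bf_load_params(f), "unknown parameter")

  bad <- doc; bad$spurious_section <- list(a = 1)
  yaml::write_yaml(bad, f)
  expect_error(bf_load_params(f), "unknown top-level")
})

test_that("ramp schedules follow the daily-increment convention", {
  s <- schedule_ramp(0.272, 3, 0.272)
  expect_equal(s$c_in, c(0.272, 0.544, 0.816))
  expect_equal(s$time_h, c(0, 24, 48))

  s30 <- schedule_ramp(0.272, 30, 0.272)
  expect_equal(schedule_value(s30, 24 * 28 + 12), 0.272 + 28 * 0.272)  # day 29

  s1 <- schedule_ramp(1.0, 1, 0.0)
  expect_equal(schedule_value(s1, c(0, 5, 23.9)), c(0, 0, 0))

  # hold-previous semantics at and between breakpoints
  s <- bf_schedule(c(0, 10, 20), c(1, 2, 3))
  expect_equal(schedule_value(s, c(0, 9.99, 10, 15, 25)), c(1, 1, 2, 2, 3))

  expect_error(schedule_ramp(-1, 5), "increment")
  expect_error(bf_schedule(c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(bf_schedule(c(0, 1), c(1, -2)), ">= 0")
})

test_that("schedules load from delimited text", {
  f <- system.file("extdata", "example_schedule.csv", package = "biofiltr")
  s <- read_schedule(f)
  expect_s3_class(s, "bf_schedule")
  expect_equal(s$c_in[1:3], c(0.272, 0.544, 0.816))
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = 1, c = 2), bad, row.names = FALSE)
  expect_error(read_schedule(bad), "columns")
})
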