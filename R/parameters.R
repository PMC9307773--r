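#' @keywords internal
"_PACKAGE"

# ---- field registries (used for validation and round-trip serialization) ----

.bf_fields <- list(
  kinetics = c("v_max", "k_s", "k_i", "mu_max", "decay_a", "yield_y", "rho_bio"),
  transport = c("henry_h", "diffusivity_d", "superficial_velocity",
                "porosity_eps", "rho_bulk", "area_a", "bed_height",
                "bed_diameter"),
  nitrogen = c("n_org", "k_min", "k_uptake", "k_n", "f_n", "n_inorg_0"),
  discretization = c("n_axial", "n_biofilm", "solver_rtol", "solver_atol",
                     "growth_concentration_mode", "advection_scheme")
)

.bf_growth_modes <- c("biofilm_average", "gas_literal", "interface")

#' Construct a validated model parameter set
#'
#' Assembles the full parameter set for the biofilter model: degradation
#' kinetics, gas/biofilm transport, the nitrogen cycle, discretization
#' controls and the initial biomass. All rate constants are in per-hour
#' units; `diffusivity_d` is the biofilm diffusivity in m^2 per hour (config
#' files accept m^2 per second and convert, see [bf_load_params()]).
#'
#' @param kinetics Named list: `v_max` (maximum specific degradation rate,
#'   g substrate / g biomass / h), `k_s` (half-saturation constant, g/m^3),
#'   `k_i` (inhibition constant, g/m^3), `mu_max` (maximum specific growth
#'   rate, 1/h), `decay_a` (decay rate, 1/h), `yield_y` (biomass yield, g/g),
#'   `rho_bio` (biofilm biomass density, g/m^3).
#' @param transport Named list: `henry_h` (dimensionless gas/biofilm
#'   partition constant), `diffusivity_d` (m^2/h), `superficial_velocity`
#'   (m/h), `porosity_eps` (bed porosity), `rho_bulk` (packing bulk density,
#'   kg compost / m^3 bed), `area_a` (specific biofilm surface area,
#'   m^2/kg compost), `bed_height` (m), `bed_diameter` (m).
#' @param nitrogen Named list: `n_org` (organic nitrogen content of the
#'   packing, g N / kg compost), `k_min` (mineralization rate constant, 1/h),
#'   `k_uptake` (background uptake rate constant, 1/h), `k_n`
#'   (Michaelis-Menten constant for nitrogen, g N / kg compost), `f_n`
#'   (nitrogen mass fraction of the degrading biomass, g N / g biomass),
#'   `n_inorg_0` (initial inorganic nitrogen, g N / kg compost).
#' @param discretization Named list: `n_axial` and `n_biofilm` (total
#'   collocation points, both counting the two boundary nodes; >= 3),
#'   `solver_rtol`, `solver_atol` (integration tolerances),
#'   `growth_concentration_mode` - which concentration drives the Haldane
#'   factor of the growth rate: `"gas_literal"` (the local gas-phase
#'   concentration, the literal form of the growth equation; default),
#'   `"biofilm_average"` (the depth-averaged factor over the biofilm
#'   profile) or `"interface"` (the biofilm surface concentration, gas/H) -
#'   and `advection_scheme`, `"collocation"` (spectral differentiation,
#'   default) or `"upwind"` (first-order monotone finite volume, the
#'   oscillation-free alternative for sharp axial fronts).
#' @param x0 Initial biomass per axial node (g biomass / kg compost), > 0.
#' @return A validated object of class `bf_params`.
#' @seealso [bf_preset()] for the three published parameter columns.
#' @export
bf_params <- function(kinetics, transport, nitrogen, discretization, x0) {
  p <- structure(
    list(kinetics = kinetics, transport = transport, nitrogen = nitrogen,
         discretization = discretization, x0 = x0),
    class = "bf_params"
  )
  validate_bf_params(p)
}

validate_bf_params <- function(p) {
  for (sec in names(.bf_fields)) {
    got <- names(p[[sec]])
    want <- .bf_fields[[sec]]
    missing <- setdiff(want, got)
    if (length(missing)) {
      stop("missing parameter(s) in `", sec, "`: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(got, want)
    if (length(unknown)) {
      stop("unknown parameter(s) in `", sec, "`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  k <- p$kinetics; tr <- p$transport; ni <- p$nitrogen; d <- p$discretization

  .positive <- function(vals, where) {
    for (nm in names(vals)) {
      v <- vals[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
        stop("`", where, "$", nm, "` must be a single positive number",
             call. = FALSE)
      }
    }
  }
  .positive(k, "kinetics")
  if (k$k_i <= k$k_s) {
    stop("`k_i` must exceed `k_s` (the Haldane rate needs an interior maximum)",
         call. = FALSE)
  }
  .positive(tr[setdiff(names(tr), "porosity_eps")], "transport")
  if (!is.numeric(tr$porosity_eps) || tr$porosity_eps <= 0 || tr$porosity_eps >= 1) {
    stop("`porosity_eps` must lie strictly between 0 and 1", call. = FALSE)
  }
  for (nm in names(ni)) {
    v <- ni[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`nitrogen$", nm, "` must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (ni$f_n > 1) stop("`f_n` is a mass fraction and cannot exceed 1", call. = FALSE)
  if (d$n_axial < 3 || d$n_biofilm < 3) {
    stop("`n_axial` and `n_biofilm` must each be >= 3", call. = FALSE)
  }
  if (!d$growth_concentration_mode %in% .bf_growth_modes) {
    stop("`growth_concentration_mode` must be one of: ",
         paste(.bf_growth_modes, collapse = ", "), call. = FALSE)
  }
  if (!d$advection_scheme %in% c("collocation", "upwind")) {
    stop("`advection_scheme` must be \"collocation\" or \"upwind\"",
         call. = FALSE)
  }
  .positive(list(solver_rtol = d$solver_rtol, solver_atol = d$solver_atol),
            "discretization")
  if (!is.numeric(p$x0) || length(p$x0) != 1L || p$x0 <= 0) {
    stop("`x0` must be a single positive number", call. = FALSE)
  }
  p
}

# shared Table-of-constants values; the three presets differ only in the
# biofilm surface area, biofilm diffusivity and packing bulk density
.bf_preset_base <- function() {
  list(
    kinetics = list(v_max = 0.3, k_s = 0.05, k_i = 2.7, mu_max = 0.1,
                    decay_a = 0.0014, yield_y = 0.5, rho_bio = 1e5),
    transport = list(henry_h = 0.25, diffusivity_d = NA_real_,
                     superficial_velocity = 3.63, porosity_eps = 0.55,
                     rho_bulk = NA_real_, area_a = NA_real_,
                     bed_height = 0.25, bed_diameter = 0.10),
    nitrogen = list(n_org = 14.98, k_min = 0.00007, k_uptake = 0.0022,
                    k_n = 0.5, f_n = 0.126, n_inorg_0 = 0.916),
    discretization = list(n_axial = 25L, n_biofilm = 10L,
                          solver_rtol = 1e-6, solver_atol = 1e-9,
                          growth_concentration_mode = "gas_literal",
                          advection_scheme = "collocation"),
    x0 = 0.003
  )
}

.bf_presets <- list(
  # diffusivities are stored in m^2/s as published and converted below
  two_steady_states    = list(area_a = 0.95,   diff_m2_s = 1.5e-10, rho_bulk = 555),
  steady_increase      = list(area_a = 1.1,    diff_m2_s = 1.5e-11, rho_bulk = 555),
  biofilter_experiment = list(area_a = 0.2375, diff_m2_s = 1.5e-12, rho_bulk = 306)
)

#' Published parameter presets
#'
#' Returns one of the three complete parameter columns used for the toluene
#' biofilter simulations: `"two_steady_states"` (the configuration whose
#' biofilm admits two coexisting steady states), `"steady_increase"` (the
#' steadily ramped inlet-concentration run) and `"biofilter_experiment"`
#' (the second, straw-packed validation column). The three columns share all
#' kinetic and nitrogen constants and differ only in biofilm surface area,
#' biofilm diffusivity and packing bulk density.
#'
#' @param name One of `"two_steady_states"`, `"steady_increase"`,
#'   `"biofilter_experiment"`.
#' @return A `bf_params` object.
#' @examples
#' p <- bf_preset("steady_increase")
#' p$transport$area_a            # 1.1 m^2/kg
#' p$transport$diffusivity_d     # 1.5e-11 m^2/s expressed in m^2/h
#' @export
bf_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.bf_presets)) {
    stop("unknown preset; available: ",
         paste(names(.bf_presets), collapse = ", "), call. = FALSE)
  }
  base <- .bf_preset_base()
  ov <- .bf_presets[[name]]
  base$transport$area_a <- ov$area_a
  base$transport$diffusivity_d <- ov$diff_m2_s * 3600   # m^2/s -> m^2/h
  base$transport$rho_bulk <- ov$rho_bulk
  do.call(bf_params, base)
}

#' Load model parameters from a YAML config
#'
#' Reads a structured config document with sections `kinetics`, `transport`,
#' `nitrogen`, `discretization` and a top-level `x0`. The transport section
#' accepts the diffusivity either as `diffusivity_m2_s` (m^2 per second, as
#' usually tabulated) or as `diffusivity_d` (already in the internal m^2 per
#' hour); a value given in m^2/s is multiplied by 3600 on load. Unknown keys
#' are rejected.
#'
#' @param path Path to a YAML file.
#' @return A validated `bf_params` object.
#' @seealso [bf_save_params()] for the inverse.
#' @export
bf_load_params <- function(path) {
  doc <- yaml::read_yaml(path)
  top_want <- c(names(.bf_fields), "x0")
  unknown <- setdiff(names(doc), top_want)
  if (length(unknown)) {
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(top_want, names(doc))
  if (length(missing)) {
    stop("missing top-level key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tr <- doc$transport
  if (!is.null(tr$diffusivity_m2_s)) {
    if (!is.null(tr$diffusivity_d)) {
      stop("give either `diffusivity_m2_s` or `diffusivity_d`, not both",
           call. = FALSE)
    }
    tr$diffusivity_d <- tr$diffusivity_m2_s * 3600
    tr$diffusivity_m2_s <- NULL
  }
  doc$transport <- tr
  d <- doc$discretization
  d$n_axial <- as.integer(d$n_axial)
  d$n_biofilm <- as.integer(d$n_biofilm)
  doc$discretization <- d
  bf_params(doc$kinetics, doc$transport, doc$nitrogen, doc$discretization,
            doc$x0)
}

#' Write model parameters to a YAML config
#'
#' Serializes a `bf_params` object so that [bf_load_params()] reproduces it
#' exactly. The diffusivity is written as `diffusivity_m2_s` (the published
#' unit) by dividing the internal m^2/h value by 3600.
#'
#' @param params A `bf_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
bf_save_params <- function(params, path) {
  stopifnot(inherits(params, "bf_params"))
  doc <- unclass(params)
  doc$transport$diffusivity_m2_s <- doc$transport$diffusivity_d / 3600
  doc$transport$diffusivity_d <- NULL
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @export
print.bf_params <- function(x, ...) {
  cat("<bf_params>\n")
  for (sec in names(.bf_fields)) {
    vals <- vapply(x[[sec]], function(v) format(v, digits = 6), character(1))
    cat("  ", sec, ": ", paste(names(vals), vals, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  cat("  x0 =", x$x0, "g/kg\n")
  invisible(x)
}

# ---- inlet schedules --------------------------------------------------------

#' Piecewise-constant inlet concentration schedule
#'
#' A schedule is a set of breakpoints `(time_h, c_in)` with hold-previous
#' semantics: the inlet concentration between two breakpoints is the value at
#' the earlier one.
#'
#' @param time_h Strictly increasing breakpoint times in hours.
#' @param c_in Inlet concentrations (g/m^3), non-negative, same length.
#' @return An object of class `bf_schedule`.
#' @export
bf_schedule <- function(time_h, c_in) {
  if (length(time_h) != length(c_in) || length(time_h) < 1L) {
    stop("`time_h` and `c_in` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(diff(time_h) <= 0)) {
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  }
  if (any(c_in < 0)) stop("inlet concentrations must be >= 0", call. = FALSE)
  structure(list(time_h = as.numeric(time_h), c_in = as.numeric(c_in)),
            class = "bf_schedule")
}

#' Daily ramp schedule
#'
#' Builds the steadily increasing inlet schedule used in the ramp scenario:
#' the inlet is constant within each 24 h day and increases by `increment`
#' at each day boundary, so day d (1-based) carries
#' `start_day_value + (d - 1) * increment`.
#'
#' @param increment Daily increase in g/m^3 (> 0).
#' @param n_days Number of days (>= 1).
#' @param start_day_value Concentration on day 1 (defaults to one increment).
#' @return A `bf_schedule` with one breakpoint per day.
#' @examples
#' schedule_ramp(0.272, 3)   # 0.272, 0.544, 0.816 g/m^3 on days 1-3
#' @export
schedule_ramp <- function(increment, n_days, start_day_value = increment) {
  if (increment <= 0) stop("`increment` must be > 0", call. = FALSE)
  if (n_days < 1) stop("`n_days` must be >= 1", call. = FALSE)
  d <- seq_len(n_days)
  bf_schedule(time_h = (d - 1) * 24, c_in = start_day_value + (d - 1) * increment)
}

#' Evaluate a schedule
#'
#' @param schedule A `bf_schedule`.
#' @param t Times in hours (vectorized). Times before the first breakpoint
#'   return the first value.
#' @return Inlet concentrations at `t` (g/m^3).
#' @export
schedule_value <- function(schedule, t) {
  stopifnot(inherits(schedule, "bf_schedule"))
  idx <- findInterval(t, schedule$time_h)
  idx[idx < 1L] <- 1L
  schedule$c_in[idx]
}

#' Read an inlet schedule from delimited text
#'
#' Expects a comma-separated file with a header row and two columns,
#' `time_h` and `c_in_g_per_m3`.
#'
#' @param path File path.
#' @return A `bf_schedule`.
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "c_in_g_per_m3")
  if (!all(need %in% names(df))) {
    stop("schedule file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bf_schedule(df$time_h, df$c_in_g_per_m3)
}
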