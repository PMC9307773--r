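#' Specific growth rate of the degrading biomass
#'
#' Haldane dependence on the carbon substrate multiplied by a Monod
#' dependence on inorganic nitrogen:
#' `mu = mu_max * c / (k_s + c + c^2/k_i) * n / (k_n + n)`.
#' The net rate is `mu - decay_a`; callers subtract the decay term where the
#' biomass balance needs it.
#'
#' @param c_local Substrate concentration driving growth (g/m^3), >= 0.
#'   Which concentration this is (local biofilm value or gas-phase value)
#'   is the caller's choice; see `growth_concentration_mode`.
#' @param n_inorg Inorganic nitrogen (g N / kg compost), >= 0.
#' @param params A `bf_params` object.
#' @return Gross specific growth rate mu (1/h), vectorized over `c_local`.
#' @export
specific_growth <- function(c_local, n_inorg, params) {
  k <- params$kinetics
  nn <- pmax(n_inorg, 0)
  k$mu_max * .haldane_factor(c_local, k$k_s, k$k_i) *
    nn / (params$nitrogen$k_n + nn)
}

#' Time derivative of inorganic nitrogen in the packing
#'
#' Mineralization of organic nitrogen minus background uptake minus uptake
#' into growing biomass:
#' `dN/dt = k_min * n_org - k_uptake * N - mu_bar * f_n * rho_bio * A * L`.
#' The biomass-uptake term uses the gross growth rate (decay returns
#' nitrogen to the organic pool and is not subtracted here).
#'
#' @param n_inorg Inorganic nitrogen (g N / kg compost).
#' @param mu_bar Gross specific growth rate averaged over the biofilm (1/h).
#' @param thickness_l Biofilm thickness L (m).
#' @param params A `bf_params` object.
#' @return dN/dt (g N / kg compost / h).
#' @export
nitrogen_rhs <- function(n_inorg, mu_bar, thickness_l, params) {
  ni <- params$nitrogen
  r_n <- mu_bar * ni$f_n * params$kinetics$rho_bio *
    params$transport$area_a * thickness_l
  ni$k_min * ni$n_org - ni$k_uptake * n_inorg - r_n
}

#' Biofilm thickness implied by areal biomass
#'
#' `L = X / (A * rho_bio)`: the biomass per kg of packing spread over the
#' specific biofilm area at the biofilm density.
#'
#' @param biomass_x Biomass (g / kg compost), >= 0.
#' @param params A `bf_params` object.
#' @return Thickness L (m).
#' @export
thickness_from_biomass <- function(biomass_x, params) {
  biomass_x / (params$transport$area_a * params$kinetics$rho_bio)
}

# thickness below which the biofilm is bypassed entirely (the depth
# equation divides by L^2)
.L_DEGENERATE <- 1e-12

# ---- state packing ----------------------------------------------------------
#
# packed state vector (length (Na-1) + (Nb-2)*Na + 2*Na):
#   [gas at axial nodes 2..Na]                    -- inlet node pinned
#   [film interior nodes, (Nb-2) x Na col-major]  -- surface pinned, substratum
#                                                    implied by zero flux
#   [biomass X at axial nodes 1..Na]
#   [inorganic N at axial nodes 1..Na]

.column_ctx <- function(params) {
  d <- params$discretization
  gb <- colloc_grid(d$n_biofilm - 2L)
  ga <- colloc_grid(d$n_axial - 2L)
  Na <- ga$n; Nb <- gb$n
  n_gas <- Na - 1L
  n_film <- (Nb - 2L) * Na
  list(
    grid_b = gb, grid_a = ga, Na = Na, Nb = Nb,
    idx_gas = seq_len(n_gas),
    idx_film = n_gas + seq_len(n_film),
    idx_X = n_gas + n_film + seq_len(Na),
    idx_N = n_gas + n_film + Na + seq_len(Na),
    n_state = n_gas + n_film + 2L * Na,
    d1f = gb$d1[1, 2:(Nb - 1), drop = FALSE],  # substratum substitution row
    d1_1 = gb$d1[1, 1], d1_n = gb$d1[1, Nb]
  )
}

# full Nb x Na film concentration matrix from packed state + gas vector
.film_matrix <- function(U, cg, ctx, params) {
  cs <- cg / params$transport$henry_h
  c1 <- -(drop(ctx$d1f %*% U) + ctx$d1_n * cs) / ctx$d1_1
  rbind(c1, U, cs, deparse.level = 0)
}

.column_rhs_core <- function(t, y, ctx, c_in, params, counter = NULL) {
  k <- params$kinetics; tr <- params$transport; ni <- params$nitrogen
  Na <- ctx$Na; Nb <- ctx$Nb
  cg <- c(c_in, y[ctx$idx_gas])
  U <- matrix(y[ctx$idx_film], Nb - 2L, Na)
  X <- y[ctx$idx_X]
  N <- y[ctx$idx_N]
  L <- X / (tr$area_a * k$rho_bio)
  active <- L >= .L_DEGENERATE

  C <- .film_matrix(U, cg, ctx, params)
  if (!is.null(counter) && any(C < -1e-12)) counter$neg <- counter$neg + 1L
  Fh <- .haldane_factor(C, k$k_s, k$k_i)
  R <- k$v_max * k$rho_bio * Fh                      # volumetric rate, Nb x Na

  Linv2 <- ifelse(active, 1 / pmax(L, .L_DEGENERATE)^2, 0)
  dC <- (ctx$grid_b$d2 %*% C) * rep(tr$diffusivity_d * Linv2, each = Nb) - R
  dU <- dC[2:(Nb - 1L), , drop = FALSE]
  if (any(!active)) dU[, !active] <- 0

  rbar <- drop(ctx$grid_b$quad_weights %*% R)        # depth-averaged rate
  sink <- tr$rho_bulk * tr$area_a * L * rbar
  sink[!active] <- 0
  adv <- if (params$discretization$advection_scheme == "upwind") {
    # first-order upwind on the same node set (monotone, positivity-preserving)
    c(0, diff(cg) / diff(ctx$grid_a$nodes))
  } else {
    drop(ctx$grid_a$d1 %*% cg)
  }
  dcg <- (-tr$superficial_velocity * adv / tr$bed_height -
            sink) / tr$porosity_eps

  Npos <- pmax(N, 0)
  nfac <- Npos / (ni$k_n + Npos)
  if (params$discretization$growth_concentration_mode == "biofilm_average") {
    fh <- drop(ctx$grid_b$quad_weights %*% Fh)
    if (any(!active)) {
      # film bypassed: kinetic-limited, concentration equals the surface value
      cs <- pmax(cg[!active], 0) / tr$henry_h
      fh[!active] <- .haldane_factor(cs, k$k_s, k$k_i)
    }
  } else if (params$discretization$growth_concentration_mode == "interface") {
    fh <- .haldane_factor(cg / tr$henry_h, k$k_s, k$k_i)
  } else {
    fh <- .haldane_factor(cg, k$k_s, k$k_i)
  }
  mu <- k$mu_max * pmax(fh, 0) * nfac
  dX <- (mu - k$decay_a) * X
  dN <- ni$k_min * ni$n_org - ni$k_uptake * Npos -
    mu * ni$f_n * k$rho_bio * tr$area_a * L

  c(dcg[-1L], as.vector(dU), dX, dN)
}

#' Time derivative of the full column state
#'
#' Assembles the coupled right-hand side: plug-flow advection of the gas
#' phase with the inlet node pinned to the schedule value, reaction-diffusion
#' in one biofilm per axial node (surface pinned through Henry's law, zero
#' flux at the substratum), exponential biomass growth/decay, and the
#' inorganic-nitrogen balance. Operates on the packed state vector used by
#' [simulate_biofilter()] (gas at axial nodes 2..n_axial, then the film
#' interior nodes column-major, then biomass, then nitrogen).
#'
#' @param t Time (h).
#' @param y Packed state vector.
#' @param schedule A `bf_schedule` giving the inlet concentration.
#' @param params A `bf_params` object.
#' @return Packed state derivative vector.
#' @export
column_rhs <- function(t, y, schedule, params) {
  ctx <- .column_ctx(params)
  stopifnot(length(y) == ctx$n_state)
  .column_rhs_core(t, y, ctx, schedule_value(schedule, t), params)
}

#' Initial packed state for a clean bed
#'
#' Gas and biofilm concentrations at zero, biomass at `x0` and inorganic
#' nitrogen at `n_inorg_0` at every axial node.
#'
#' @param params A `bf_params` object.
#' @return Packed state vector.
#' @export
initial_state <- function(params) {
  ctx <- .column_ctx(params)
  y <- numeric(ctx$n_state)
  y[ctx$idx_X] <- params$x0
  y[ctx$idx_N] <- params$nitrogen$n_inorg_0
  y
}

#' Simulate the biofilter through an inlet schedule
#'
#' Integrates the coupled gas/biofilm/biomass/nitrogen system with a stiff
#' solver (`deSolve`, sparse-Jacobian BDF), restarting cleanly at every
#' schedule breakpoint so the piecewise-constant inlet enters exactly.
#' Sampled outputs and full state snapshots are recorded every
#' `sample_every` hours; a sample that falls on a day boundary is reported
#' against the inlet value of the day just ended, so end-of-day removal
#' efficiencies are well defined.
#'
#' @param schedule A `bf_schedule`.
#' @param params A `bf_params` object.
#' @param t_end End time (h), > `t0`.
#' @param sample_every Output sampling interval (h), default 1.
#' @param init Optional packed initial state (e.g. [final_state()] of an
#'   earlier run); defaults to the clean-bed [initial_state()].
#' @param t0 Start time (h), default 0.
#' @param method `deSolve` integration method; default `"lsodes"`.
#' @return An object of class `bf_result`: a list with
#'   \describe{
#'     \item{table}{data.frame `time_h, day, c_in, c_out, re_percent,
#'       mean_thickness_m, mean_biomass, mean_n_inorg`}
#'     \item{snapshots}{matrix of full packed states, one row per sample
#'       (first column = time)}
#'     \item{params, schedule}{the inputs}
#'     \item{neg_clamp_events}{number of RHS evaluations in which a negative
#'       concentration excursion was clamped}
#'   }
#' @export
simulate_biofilter <- function(schedule, params, t_end, sample_every = 1,
                               init = NULL, t0 = 0, method = "lsodes") {
  stopifnot(inherits(schedule, "bf_schedule"), inherits(params, "bf_params"),
            t_end > t0, sample_every > 0)
  ctx <- .column_ctx(params)
  y <- if (is.null(init)) initial_state(params) else init
  stopifnot(length(y) == ctx$n_state)
  d <- params$discretization
  counter <- new.env(parent = emptyenv())
  counter$neg <- 0L

  breaks <- schedule$time_h
  seg_edges <- sort(unique(c(t0, breaks[breaks > t0 & breaks < t_end], t_end)))
  samples <- seq(t0, t_end, by = sample_every)
  if (samples[length(samples)] < t_end) samples <- c(samples, t_end)

  snap_rows <- list()
  tab_rows <- list()
  record <- function(tt, yy, c_in) {
    X <- yy[ctx$idx_X]
    L <- X / (params$transport$area_a * params$kinetics$rho_bio)
    c_out <- yy[ctx$idx_gas][ctx$Na - 1L]
    re <- if (c_in > 0) 100 * (c_in - c_out) / c_in else NA_real_
    tab_rows[[length(tab_rows) + 1L]] <<- data.frame(
      time_h = tt, day = floor((tt - 1e-9) / 24) + 1L, c_in = c_in,
      c_out = c_out, re_percent = re, mean_thickness_m = mean(L),
      mean_biomass = mean(X), mean_n_inorg = mean(yy[ctx$idx_N]))
    snap_rows[[length(snap_rows) + 1L]] <<- c(tt, yy)
  }

  for (s in seq_len(length(seg_edges) - 1L)) {
    a <- seg_edges[s]; b <- seg_edges[s + 1L]
    c_in <- schedule_value(schedule, a)
    tt <- sort(unique(c(a, samples[samples > a & samples <= b], b)))
    rhs <- function(t, yv, p) list(.column_rhs_core(t, yv, ctx, c_in, params, counter))
    out <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = method, rtol = d$solver_rtol,
                        atol = d$solver_atol, maxsteps = 100000)
    if (attr(out, "istate")[1] < 0) {
      stop("integration failed in segment [", a, ", ", b, "] h; last time ",
           max(out[, 1]), call. = FALSE)
    }
    keep <- which(out[, 1] %in% samples | out[, 1] == b)
    for (i in keep) record(out[i, 1], out[i, -1], c_in)
    y <- out[nrow(out), -1]
  }

  tab <- do.call(rbind, tab_rows)
  # segment endpoints appear twice (end of one segment, start of next);
  # keep the first occurrence so boundary rows carry the just-ended inlet
  dup <- duplicated(tab$time_h)
  structure(
    list(table = tab[!dup, , drop = FALSE],
         snapshots = do.call(rbind, snap_rows)[!dup, , drop = FALSE],
         params = params, schedule = schedule,
         neg_clamp_events = counter$neg),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  tb <- x$table
  cat("<bf_result> ", nrow(tb), " samples, t = ", min(tb$time_h), "..",
      max(tb$time_h), " h\n", sep = "")
  cat("  final: c_in=", format(tb$c_in[nrow(tb)], digits = 4),
      " c_out=", format(tb$c_out[nrow(tb)], digits = 4),
      " RE=", format(tb$re_percent[nrow(tb)], digits = 4), "%\n", sep = "")
  invisible(x)
}

#' Final packed state of a simulation
#'
#' @param result A `bf_result`.
#' @return Packed state vector usable as `init` in [simulate_biofilter()].
#' @export
final_state <- function(result) {
  sn <- result$snapshots
  as.numeric(sn[nrow(sn), -1])
}

#' Unpack a snapshot into named column state
#'
#' @param result A `bf_result`.
#' @param time Requested time (h); the nearest recorded snapshot is used
#'   (error if none lies within one sampling interval).
#' @return List: `time`, `c_in`, `c_gas` (length n_axial, inlet first),
#'   `films` (n_biofilm x n_axial full concentration profiles), `biomass_x`,
#'   `n_inorg`, `thickness_l` (all per axial node).
#' @export
state_at <- function(result, time) {
  sn <- result$snapshots
  i <- which.min(abs(sn[, 1] - time))
  if (abs(sn[i, 1] - time) > max(diff(sort(sn[, 1])))) {
    stop("no snapshot near t = ", time, " h", call. = FALSE)
  }
  params <- result$params
  ctx <- .column_ctx(params)
  y <- as.numeric(sn[i, -1])
  c_in <- result$table$c_in[i]
  cg <- c(c_in, y[ctx$idx_gas])
  U <- matrix(y[ctx$idx_film], ctx$Nb - 2L, ctx$Na)
  X <- y[ctx$idx_X]
  list(time = sn[i, 1], c_in = c_in, c_gas = cg,
       films = .film_matrix(U, cg, ctx, params),
       biomass_x = X, n_inorg = y[ctx$idx_N],
       thickness_l = thickness_from_biomass(X, params))
}

#' Biofilm concentration profile at a time and axial position
#'
#' Extracts the biofilm profile at one axial collocation point from the
#' recorded snapshots, with the dimensionless depth converted to physical
#' depth from the substratum (`x' * L`).
#'
#' @param result A `bf_result`.
#' @param time Time (h); nearest snapshot is used.
#' @param axial_index Axial node index, 1 (inlet) .. n_axial (outlet).
#' @return data.frame `x_prime, depth_m, c_biofilm`, substratum first.
#' @export
biofilm_profile_at <- function(result, time, axial_index) {
  st <- state_at(result, time)
  ctx <- .column_ctx(result$params)
  if (axial_index < 1 || axial_index > ctx$Na) {
    stop("`axial_index` must be in 1..", ctx$Na, call. = FALSE)
  }
  gb <- ctx$grid_b
  data.frame(x_prime = gb$nodes,
             depth_m = gb$nodes * st$thickness_l[axial_index],
             c_biofilm = st$films[, axial_index])
}

#' Write simulated trajectories to delimited text
#'
#' @param result A `bf_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
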