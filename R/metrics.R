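#' Biofilter performance metrics
#'
#' The four standard descriptors: removal efficiency
#' `RE = 100 (C_in - C_out) / C_in` (%), inlet loading rate
#' `ILR = Q C_in / V` (g/m^3/h), elimination capacity
#' `EC = Q (C_in - C_out) / V` (g/m^3/h) and empty-bed residence time
#' `EBRT = V / Q` (reported in minutes).
#'
#' @param c_in Inlet concentration (g/m^3), > 0.
#' @param c_out Outlet concentration (g/m^3), >= 0.
#' @param flow_q Volumetric gas flow (m^3/h), > 0.
#' @param volume_v Bed volume (m^3), > 0.
#' @return data.frame `c_in, c_out, flow_q, volume_v, re, ilr, ec, ebrt_min`.
#' @examples
#' performance(10, 5, 0.026, 1.96e-3)
#' @export
performance <- function(c_in, c_out, flow_q, volume_v) {
  if (any(c_in <= 0)) stop("RE is undefined for `c_in` <= 0", call. = FALSE)
  if (any(flow_q <= 0) || any(volume_v <= 0)) {
    stop("`flow_q` and `volume_v` must be > 0", call. = FALSE)
  }
  if (any(c_out < 0)) stop("`c_out` must be >= 0", call. = FALSE)
  re <- 100 * (c_in - c_out) / c_in
  ilr <- flow_q * c_in / volume_v
  ec <- flow_q * (c_in - c_out) / volume_v
  data.frame(c_in = c_in, c_out = c_out, flow_q = flow_q,
             volume_v = volume_v, re = re, ilr = ilr, ec = ec,
             ebrt_min = 60 * volume_v / flow_q)
}

#' Compare simulated outlet to an observed series
#'
#' Linearly interpolates the simulated outlet concentration to the
#' observation times and reports the root-mean-square error and the
#' coefficient of determination `r^2 = 1 - SS_res / SS_tot` (about the
#' observed mean).
#'
#' @param model A `bf_result`, or a data.frame with columns `time_h`
#'   and `c_out`.
#' @param observed data.frame with columns `time_h` and `c_out`.
#' @return data.frame `rmse` (g/m^3), `r_squared`, `n_points`.
#' @export
compare_series <- function(model, observed) {
  tb <- if (inherits(model, "bf_result")) model$table else model
  stopifnot(all(c("time_h", "c_out") %in% names(tb)),
            all(c("time_h", "c_out") %in% names(observed)))
  inside <- observed$time_h >= min(tb$time_h) & observed$time_h <= max(tb$time_h)
  if (sum(inside) < 2) {
    stop("need at least two observation times inside the simulated span",
         call. = FALSE)
  }
  obs <- observed[inside, , drop = FALSE]
  pred <- stats::approx(tb$time_h, tb$c_out, xout = obs$time_h)$y
  resid <- obs$c_out - pred
  rmse <- sqrt(mean(resid^2))
  ss_tot <- sum((obs$c_out - mean(obs$c_out))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  data.frame(rmse = rmse, r_squared = r2, n_points = nrow(obs))
}

#' Generate a synthetic observed outlet series
#'
#' Emulates daily gas-chromatograph sampling of the outlet: at each
#' end-of-day sample of the simulation, `n_replicates` independent Gaussian
#' draws (sd `noise_sd`) are taken around the simulated outlet and reported
#' as their mean with the replicate standard error. With the default
#' triplicates and sd 0.10 g/m^3 the expected standard error is
#' 0.10/sqrt(3) = 0.058 g/m^3.
#'
#' @param result A `bf_result`.
#' @param noise_sd Measurement standard deviation (g/m^3), >= 0.
#' @param n_replicates Replicates per sampling time (>= 1), default 3.
#' @param seed Integer seed; the series is reproducible given the seed.
#' @return data.frame `time_h, day, c_out` (replicate mean), `se`
#'   (replicate standard error; NA for a single replicate).
#' @export
synthesize_observations <- function(result, noise_sd = 0.10,
                                    n_replicates = 3L, seed = 1L) {
  stopifnot(noise_sd >= 0, n_replicates >= 1)
  tb <- daily_summary(result)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- matrix(stats::rnorm(nrow(tb) * n_replicates, mean = rep(tb$c_out, each = n_replicates),
                               sd = noise_sd),
                  nrow = n_replicates)
  data.frame(
    time_h = tb$time_h, day = tb$day,
    c_out = colMeans(draws),
    se = if (n_replicates > 1) apply(draws, 2, stats::sd) / sqrt(n_replicates)
         else NA_real_
  )
}

#' End-of-day summary of a simulation
#'
#' One row per simulated day, taken at the last sample of that day (the
#' daily reporting convention: within-day transients after each inlet step
#' are excluded).
#'
#' @param result A `bf_result`.
#' @return data.frame with the columns of `result$table`, one row per day.
#' @export
daily_summary <- function(result) {
  tb <- result$table
  tb <- tb[tb$day >= 1, , drop = FALSE]
  idx <- tapply(seq_len(nrow(tb)), tb$day, function(i) i[which.max(tb$time_h[i])])
  out <- tb[unlist(idx), , drop = FALSE]
  out[order(out$day), , drop = FALSE]
}
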