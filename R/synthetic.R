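# Synthetic experiment generators. Every experimental input the pipeline
# consumes (binodal points, void-count experiments, FRAP traces, fusion
# events) can be generated from a known ground truth, so each stage is
# testable end to end without measured data. All generators are pure
# functions of their arguments and the seed.
#
# Default designs mirror the experiments being emulated: binodal points for
# both phases over the two-phase temperature range; condensates of 10-100 um
# diameter (log-uniform) cooled from 55 to 36 C at rates of 0.5-5 K/min;
# FRAP spots and fusing condensate pairs in the 5-20 um range. Noise models:
# Gaussian relative noise for concentrations/intensities/aspect ratios,
# Poisson for void counts.

#' Generate synthetic binodal measurements
#'
#' True coexistence concentrations of `model` at the requested temperatures
#' plus Gaussian relative noise, for both phases.
#'
#' @param model ground-truth [phase_model()]
#' @param temps_C measurement temperatures (deg C), below the critical point
#' @param rel_noise relative noise scale (standard deviation / value)
#' @param seed RNG seed
#' @return data.frame with `T` (K), `phase`, `conc` (kg/m^3), `sigma`
#'   (kg/m^3) -- the schema consumed by [fit_phase_model()]
#' @export
gen_binodal_points <- function(model, temps_C = seq(20, 60, by = 5),
                               rel_noise = 0.05, seed = 1) {
  stopifnot(rel_noise >= 0)
  T <- celsius_to_kelvin(temps_C)
  if (any(T >= critical_point(model)$T_c)) {
    stop("all temperatures must lie below the critical temperature")
  }
  set.seed(seed)
  bc <- binodal_curve(T, model)
  true_conc <- c(bc$phi_minus, bc$phi_plus) * model$rho_solute
  out <- data.frame(
    T = rep(T, 2),
    phase = rep(c("dilute", "dense"), each = length(T)),
    conc = true_conc * (1 + stats::rnorm(2 * length(T), 0, rel_noise)),
    sigma = true_conc * rel_noise)
  out$conc <- pmax(out$conc, 1e-6) # concentrations stay positive
  out
}

#' Generate a synthetic void-count experiment
#'
#' For each cooling rate, condensate diameters are drawn log-uniformly from
#' `d_range`; the expected void count N(d) is computed from the ground-truth
#' transport + nucleation model on a log-spaced diameter grid (`n_interp`
#' trajectory simulations per rate) and interpolated; observed counts are
#' Poisson draws with mean N.
#'
#' @param model ground-truth [phase_model()]
#' @param tension ground-truth [tension_model()]
#' @param kin ground-truth [kinetic_params()] (theta is the truth value)
#' @param rates cooling rates (K/s); default 0.5, 1, 2, 5 K/min
#' @param n_per_rate condensates per cooling rate
#' @param d_range diameter range (m), log-uniform sampling
#' @param T0,T_end protocol temperatures (K)
#' @param n_interp diameters at which N is simulated exactly (per rate)
#' @param transport extra arguments for [simulate_condensate()]
#' @param seed RNG seed
#' @return data.frame with `cooling_rate` (K/s), `diameter` (m), `n_voids`,
#'   `N_true`; the ground-truth parameters are attached as attribute
#'   `truth`
#' @export
gen_void_experiment <- function(model, tension, kin,
                                rates = c(0.5, 1, 2, 5) / 60,
                                n_per_rate = 60,
                                d_range = c(10e-6, 100e-6),
                                T0 = celsius_to_kelvin(55),
                                T_end = celsius_to_kelvin(36),
                                n_interp = 12, transport = list(),
                                seed = 1) {
  stopifnot(length(rates) >= 1, n_per_rate >= 1, d_range[1] < d_range[2])
  set.seed(seed)
  Tc <- critical_point(model)$T_c
  d_grid <- exp(seq(log(d_range[1]), log(d_range[2]), length.out = n_interp))
  out <- vector("list", length(rates))
  for (k in seq_along(rates)) {
    N_grid <- vapply(d_grid, function(d)
      expected_voids_at_diameter(d, rates[k], model, tension, kin,
                                 T0, T_end, transport), numeric(1))
    # N(d) is smooth and monotone in log-log; interpolate the simulated grid
    lnN <- stats::splinefun(log(d_grid), log(pmax(N_grid, 1e-300)),
                            method = "hyman")
    d <- exp(stats::runif(n_per_rate, log(d_range[1]), log(d_range[2])))
    N <- exp(lnN(log(d)))
    N[N < 1e-250] <- 0 # clamped-underflow grid values mean "no nucleation"
    out[[k]] <- data.frame(cooling_rate = rates[k], diameter = d,
                           n_voids = stats::rpois(n_per_rate, N),
                           N_true = N)
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- list(gamma0 = tension$gamma0,
                             tension_form = tension$form,
                             theta = kin$theta)
  res
}

#' Generate synthetic FRAP traces
#'
#' Exact single-exponential recovery curves
#' \eqn{I(t) = I_{final} - (I_{final} - I_{start}) e^{-t/\tau}} with
#' \eqn{\tau = d^2 / (16 D)} set by the ground-truth diffusivity, plus
#' multiplicative Gaussian noise.
#'
#' @param D_true ground-truth diffusivity (m^2/s)
#' @param spot_diameters bleach-spot diameters (m)
#' @param n_points time points per trace
#' @param rel_noise relative intensity noise
#' @param I_start,I_final bleached and recovered intensity levels
#' @param seed RNG seed
#' @return list of traces (each with `spot_diameter`, `times`,
#'   `intensities`, and the truth `tau`, `D`)
#' @export
gen_frap_traces <- function(D_true = 1.3e-13,
                            spot_diameters = seq(4e-6, 20e-6, length.out = 9),
                            n_points = 60, rel_noise = 0,
                            I_start = 0.2, I_final = 1, seed = 1) {
  stopifnot(D_true > 0, all(spot_diameters > 0), rel_noise >= 0)
  set.seed(seed)
  lapply(spot_diameters, function(d) {
    tau <- d^2 / (16 * D_true)
    times <- seq(0, 5 * tau, length.out = n_points)
    I <- I_final - (I_final - I_start) * exp(-times / tau)
    list(spot_diameter = d, times = times,
         intensities = I * (1 + stats::rnorm(n_points, 0, rel_noise)),
         tau = tau, D = D_true)
  })
}

#' Generate synthetic fusion events
#'
#' Exact aspect-ratio relaxations
#' \eqn{A(t) = 1 + (A_0 - 1) e^{-t/\tau}} with
#' \eqn{\tau = (d_1 + d_2) / (2 v)} set by the ground-truth capillary
#' velocity, plus multiplicative Gaussian noise.
#'
#' @param v_true ground-truth capillary velocity (m/s)
#' @param n_events number of fusion events
#' @param d_range condensate diameter range (m)
#' @param A0 initial aspect ratio
#' @param n_points time points per event
#' @param rel_noise relative aspect-ratio noise
#' @param seed RNG seed
#' @return list of events (each with `d1`, `d2`, `times`, `aspect_ratios`,
#'   `A0`, and the truth `tau_fusion`, `v`)
#' @export
gen_fusion_events <- function(v_true = 5e-6, n_events = 12,
                              d_range = c(5e-6, 20e-6), A0 = 1.4,
                              n_points = 60, rel_noise = 0, seed = 1) {
  stopifnot(v_true > 0, n_events >= 1, A0 > 1, rel_noise >= 0)
  set.seed(seed)
  lapply(seq_len(n_events), function(i) {
    d <- stats::runif(2, d_range[1], d_range[2])
    tau <- (d[1] + d[2]) / (2 * v_true)
    times <- seq(0, 5 * tau, length.out = n_points)
    A <- 1 + (A0 - 1) * exp(-times / tau)
    list(d1 = d[1], d2 = d[2], times = times,
         aspect_ratios = A * (1 + stats::rnorm(n_points, 0, rel_noise)),
         A0 = A0, tau_fusion = tau, v = v_true)
  })
}
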