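# Reduction of raw biophysical measurements to model inputs:
# FRAP recovery -> dense-phase diffusivity, fusion relaxation -> capillary
# velocity, Stokes-Einstein -> viscosity (and gamma = v * eta).

# Least-squares fit of y = a + b exp(-t / tau) by variable projection:
# for fixed tau the amplitudes (a, b) are linear, so only log(tau) is
# optimised (coarse scan + golden-section polish). With `fix_a` the offset
# is held at a known value and only b is projected. Exact (zero-residual)
# on noiseless model data.
exp_fit <- function(t, y, fix_a = NULL) {
  stopifnot(length(t) == length(y), length(t) >= 4, all(is.finite(y)))
  span <- diff(range(t))
  if (span <= 0) stop("degenerate time axis")
  amplitudes <- function(tau) {
    e <- exp(-t / tau)
    if (is.null(fix_a)) {
      X <- cbind(1, e)
      cf <- tryCatch(unname(qr.solve(X, y)), error = function(z) c(NA, NA))
      list(a = cf[1], b = cf[2], e = e)
    } else {
      b <- sum(e * (y - fix_a)) / sum(e * e)
      list(a = fix_a, b = b, e = e)
    }
  }
  ssr <- function(log_tau) {
    am <- amplitudes(exp(log_tau))
    if (any(!is.finite(c(am$a, am$b)))) return(Inf)
    sum((y - am$a - am$b * am$e)^2)
  }
  grid <- log(span) + seq(-8, 8, length.out = 80)
  vals <- vapply(grid, ssr, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(ssr, c(lo, hi), tol = 1e-12)
  tau <- exp(opt$minimum)
  am <- amplitudes(tau)
  if (!is.finite(opt$objective)) stop("exponential fit failed to converge")
  list(tau = tau, a = am$a, b = am$b, ssr = opt$objective)
}

#' Diffusivity from a FRAP recovery trace
#'
#' Fits the single-exponential recovery
#' \eqn{I(t) = I_{final} - (I_{final} - I_{start}) e^{-t/\tau}} by least
#' squares and converts the recovery time to a diffusion coefficient with
#' \eqn{D = d^2 / (16 \tau)}, where `d` is the bleach-spot diameter.
#'
#' @param trace list (or one-row equivalent) with `spot_diameter` (m),
#'   `times` (s), `intensities` (arbitrary units, >= 5 points)
#' @return list with `tau` (s), `D` (m^2/s), `I_start`, `I_final`, `ssr`
#' @examples
#' tr <- list(spot_diameter = 10e-6, times = seq(0, 150, 2),
#'            intensities = 1 - 0.8 * exp(-seq(0, 150, 2) / 30))
#' frap_diffusivity(tr)$D # d^2/(16 tau) = 2.08e-13
#' @export
frap_diffusivity <- function(trace) {
  stopifnot(trace$spot_diameter > 0, length(trace$times) >= 5,
            length(trace$times) == length(trace$intensities))
  fit <- exp_fit(trace$times, trace$intensities)
  list(tau = fit$tau,
       D = trace$spot_diameter^2 / (16 * fit$tau),
       I_start = fit$a + fit$b, I_final = fit$a, ssr = fit$ssr)
}

#' Capillary velocity from a condensate fusion event
#'
#' Fits the aspect-ratio relaxation
#' \eqn{A(t) = 1 + (A_0 - 1) e^{-t/\tau_{fusion}}} of two fusing condensates
#' and returns the capillary velocity \eqn{v = \gamma/\eta} estimated as
#' \eqn{v = (d_1 + d_2) / (2 \tau_{fusion})}. (This is the dimensionally
#' consistent reading of the commonly quoted relation
#' "v = 2 tau / (d1 + d2)", which as printed has units of s/m.)
#'
#' @param event list with `d1`, `d2` (m), `times` (s), `aspect_ratios`
#'   (>= 1, relaxing towards 1)
#' @return list with `tau_fusion` (s), `v` (m/s), `A0`, `ssr`
#' @export
fusion_capillary_velocity <- function(event) {
  stopifnot(event$d1 > 0, event$d2 > 0,
            length(event$times) == length(event$aspect_ratios))
  if (max(event$aspect_ratios) - 1 < 1e-9) {
    stop("degenerate fusion event: aspect ratio never deviates from 1")
  }
  fit <- exp_fit(event$times, event$aspect_ratios, fix_a = 1)
  list(tau_fusion = fit$tau,
       v = (event$d1 + event$d2) / (2 * fit$tau),
       A0 = 1 + fit$b, ssr = fit$ssr)
}

#' Viscosity from diffusivity via Stokes-Einstein
#'
#' \eqn{\eta = k_B T / (6 \pi D R_h)} for a hydrodynamic radius `R_h`.
#' Combined with [fusion_capillary_velocity()], the interfacial tension
#' follows as \eqn{\gamma = v \eta}.
#'
#' @param D diffusivity (m^2/s)
#' @param T temperature (K)
#' @param R_h hydrodynamic radius (m); 5-20 nm is a realistic range for
#'   Mda-scale RNA chains
#' @return dynamic viscosity (Pa s), vectorised
#' @export
stokes_einstein_viscosity <- function(D, T, R_h) {
  stopifnot(all(D > 0), all(T > 0), all(R_h > 0))
  KB * T / (6 * pi * D * R_h)
}
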