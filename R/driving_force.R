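# Nucleation driving forces (free-energy difference per solute molecule).
#
# Sign convention: a favourable transition has a negative driving force.
# Both driving forces are returned in joules per molecule; the per-site
# Flory-Huggins free energies (k_B T units) are multiplied by k_B T here.

#' Driving force for condensate nucleation from dilute solution
#'
#' \eqn{\Delta g_+ = -k_B T \ln S} with supersaturation
#' \eqn{S = \phi / \phi_-(T)}: negative (favourable) when the solution is
#' supersaturated with respect to the dilute binodal.
#'
#' @param phi solute volume fraction of the dilute solution (> 0)
#' @param T temperature (K)
#' @param model a [phase_model()]
#' @param phi_minus optional pre-computed dilute binodal at `T` (vectorised
#'   use); computed from `model` when missing
#' @return driving force in joules per molecule (vectorised)
#' @export
delta_g_plus <- function(phi, T, model, phi_minus = NULL) {
  if (any(phi <= 0)) stop("`phi` must be positive")
  if (is.null(phi_minus)) {
    phi_minus <- if (length(T) == 1) {
      compute_binodal(T, model)$phi_minus
    } else {
      binodal_curve(T, model)$phi_minus
    }
  }
  -KB * T * log(phi / phi_minus)
}

#' Partition factor for void formation
#'
#' Volume balance for a control volume of dense phase at composition `phi`
#' splitting into void (dilute, \eqn{\phi_-}) and concentrated dense phase
#' (\eqn{\phi_+}): the ratio of molecules ending up in the dense phase to
#' those in the void is
#' \deqn{K = \frac{1/\phi - 1/\phi_-}{1/\phi_+ - 1/\phi}}
#' The lattice-site volume cancels and is not represented.
#'
#' @param phi parent dense-phase volume fraction, strictly inside
#'   `(phi_minus, phi_plus)`
#' @param phi_minus,phi_plus binodal volume fractions (e.g. from
#'   [compute_binodal()])
#' @return dimensionless partition factor K > 0 (vectorised over `phi`)
#' @export
partition_factor <- function(phi, phi_minus, phi_plus) {
  if (any(phi <= phi_minus | phi >= phi_plus)) {
    stop("`phi` must lie strictly between the binodal compositions")
  }
  (1 / phi - 1 / phi_minus) / (1 / phi_plus - 1 / phi)
}

#' Driving force for void nucleation inside a condensate
#'
#' Free-energy change per molecule transferred when a pocket of dilute phase
#' forms inside a dense phase of composition `phi`:
#' \deqn{\Delta g_- = [g(\phi_-) - g(\phi)] + K(\phi, \phi_\pm)
#'   [g(\phi_+) - g(\phi)]}
#' with \eqn{g = f M / \phi} the per-molecule free energy and K the
#' [partition_factor()]. It vanishes at both binodal compositions and is
#' negative in between (no driving force at equilibrium; void formation
#' favourable for any intermediate composition).
#'
#' Numerically the two terms are evaluated in the algebraically equivalent
#' tangent-excess form
#' \deqn{\Delta g_- = -M \, h(\phi)\, \frac{\phi_+ - \phi_-}
#'   {\phi_- (\phi_+ - \phi)} \; k_B T, \qquad
#'   h(\phi) = f(\phi) - f(\phi_-) - f'(\phi_-)(\phi - \phi_-)}
#' (h is the free-energy excess above the common tangent, which vanishes at
#' both binodals). The naive two-term evaluation suffers catastrophic
#' cancellation near the dense binodal, where K diverges while the bracket
#' it multiplies vanishes; the tangent-excess form is exact and stable.
#'
#' @param phi condensate volume fraction, within `[phi_minus, phi_plus]`
#' @param T temperature (K), scalar
#' @param model a [phase_model()]
#' @param binodal optional pre-computed result of [compute_binodal()] at `T`
#' @return driving force in joules per molecule (vectorised over `phi`)
#' @export
delta_g_minus <- function(phi, T, model, binodal = NULL) {
  if (is.null(binodal)) binodal <- compute_binodal(T, model)
  pm <- binodal$phi_minus; pp <- binodal$phi_plus
  eps <- 1e-12
  if (any(phi < pm * (1 - 1e-9) - eps | phi > pp * (1 + 1e-9) + eps)) {
    stop("`phi` must lie within the binodal interval [phi_minus, phi_plus]")
  }
  delta_g_minus_core(phi, T, pm, pp, model)
}

# Stable tangent-excess evaluation shared by the scalar interface and the
# trajectory field. Compositions within a relative 1e-9 of either binodal
# are treated as at equilibrium (driving force 0); the physical driving
# force there is < 1e-6 kBT, far below anything that matters for rates.
delta_g_minus_core <- function(phi, T, pm, pp, model) {
  out <- numeric(length(phi))
  if (pp - pm < 1e-12) return(out)
  interior <- phi > pm * (1 + 1e-9) & phi < pp * (1 - 1e-9)
  if (any(interior)) {
    p <- phi[interior]
    chi <- chi_at(T, model)
    h <- free_energy_density(p, T, model) -
      free_energy_density(pm, T, model) -
      fh_fprime(pm, chi, model$M) * (p - pm)
    out[interior] <- -model$M * pmax(h, 0) * (pp - pm) /
      (pm * (pp - p)) * KB * T
  }
  out
}
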