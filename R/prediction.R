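# Condensate-nucleation predictions: microdroplet rate lower bound,
# nucleation rate as a function of supercooling, the driving-force/tension
# atlas across condensate and solid systems, and cell-scale sensitivity.

#' Lower bound on the condensate nucleation rate from droplet counts
#'
#' Converts a measured number density of condensates formed within a time
#' window into a nucleation rate, \eqn{J \ge n / \Delta t}. A lower bound:
#' growth of the first nuclei depletes the solution and slows further
#' nucleation, and nuclei may coalesce before counting.
#'
#' @param count_density condensates per m^3 (330 per nanolitre =
#'   3.3e14 m^-3)
#' @param window formation timescale (s)
#' @return rate lower bound (m^-3 s^-1)
#' @examples
#' droplet_rate_lower_bound(330 / 1e-9 * 1e-3, 100) # 330 per nL in SI
#' @export
droplet_rate_lower_bound <- function(count_density, window) {
  stopifnot(all(count_density >= 0), all(window > 0))
  count_density / window
}

#' Condensate nucleation rate as a function of supercooling
#'
#' Sweeps the temperature downward from a reference `T_ref`, at which the
#' solution is taken to sit exactly on the dilute binodal, and evaluates at
#' each supercooling \eqn{\Delta T = T_{ref} - T}: the supersaturation
#' \eqn{S = \phi_-(T_{ref})/\phi_-(T)}, the driving force
#' \eqn{\Delta g_+ = -k_B T \ln S}, and the condensate nucleation rate
#' \eqn{J_{cond}}. The measured solution concentration `c0` enters only the
#' rate prefactor (as the parent-phase number concentration); the
#' composition reference is the binodal itself, so \eqn{\Delta g_+ = 0} and
#' \eqn{J = 0} at zero supercooling. The dense-phase molecular volume and
#' (for the scaling forms) the tension are re-evaluated at every grid
#' temperature.
#'
#' @param model a [phase_model()]
#' @param tension a [tension_model()]
#' @param kin a [kinetic_params()] (uses `theta`, `D_minus`, `Mw`)
#' @param c0 dilute-solution mass concentration (kg/m^3), used in the
#'   kinetic prefactor
#' @param T_ref reference temperature (K) defining zero supercooling; the
#'   solution composition is the dilute binodal at this temperature
#' @param dT_max largest supercooling (K), default 6
#' @param resolution supercooling grid step (K), default 0.003
#' @return data.frame with `delta_T` (K), `T` (K), `S`, `delta_g` (J per
#'   molecule), `J` (m^-3 s^-1)
#' @export
supercooling_curve <- function(model, tension, kin, c0, T_ref,
                               dT_max = 6, resolution = 0.003) {
  stopifnot(c0 > 0, T_ref < critical_point(model)$T_c)
  dT <- seq(0, dT_max, by = resolution)
  T <- T_ref - dT
  bc <- binodal_curve(T, model)
  phi0 <- bc$phi_minus[1] # solution sits on the binodal at T_ref
  S <- phi0 / bc$phi_minus
  dg <- -KB * T * log(S)
  vm_plus <- kin$Mw / (N_AVOGADRO * bc$phi_plus * model$rho_solute)
  c_num <- c0 * N_AVOGADRO / kin$Mw
  gam <- gamma_at(T, tension, model, binodal = bc)
  lnJ <- ln_nucleation_rate(gamma = gam, delta_g = dg, vm = vm_plus,
                            c_num = c_num, D = kin$D_minus,
                            theta = kin$theta, T = T)
  data.frame(delta_T = dT, T = T, S = S, delta_g = dg,
             J = ifelse(lnJ < -700, 0, exp(lnJ)))
}

#' Smallest supercooling at which a rate threshold is reached
#'
#' @param curve output of [supercooling_curve()]
#' @param threshold rate threshold (m^-3 s^-1), default 1e12 (one nucleus
#'   per 100 s per nanolitre)
#' @return smallest `delta_T` (K) with `J >= threshold`, or NA if the curve
#'   never crosses it
#' @export
supercooling_crossing <- function(curve, threshold = J_RELEVANT) {
  i <- which(curve$J >= threshold)
  if (length(i) == 0) return(NA_real_)
  curve$delta_T[min(i)]
}

#' Driving force at which nucleation becomes relevant
#'
#' Solves \eqn{J(\gamma, \Delta g) = J_{thresh}} for the driving force
#' magnitude, using the reference parameter set of the tension atlas
#' (mass concentration 1 mg/mL, T = 300 K, solute density 1.5 g/mL,
#' D = 1e-10 m^2/s, dense-phase volume fraction 0.2 for condensates and 0.5
#' for solids, theta = 1 for homogeneous nucleation). Root-finding is on
#' \eqn{\ln J}, which is strictly increasing in \eqn{|\Delta g|}.
#'
#' @param gamma interfacial tension (J/m^2)
#' @param Mw molecular weight (kg/mol)
#' @param phi dense/solid-phase volume fraction (0.2 condensates, 0.5 solids)
#' @param theta kinetic prefactor (default 1)
#' @param mass_conc parent-solution mass concentration (kg/m^3), default 1
#' @param T temperature (K), default 300
#' @param rho_solute solute density (kg/m^3), default 1500
#' @param D solute diffusivity in the parent solution (m^2/s), default 1e-10
#' @param threshold rate defining "relevant" (m^-3 s^-1), default 1e12
#' @return driving force magnitude in J/mol
#' @examples
#' delta_g_min(1.8e-6, Mw = 2500) # well below RT = 2.5 kJ/mol
#' @export
delta_g_min <- function(gamma, Mw, phi = 0.2, theta = 1, mass_conc = 1,
                        T = 300, rho_solute = 1500, D = 1e-10,
                        threshold = J_RELEVANT) {
  stopifnot(gamma > 0, Mw > 0, phi > 0, phi < 1)
  vm <- Mw / (N_AVOGADRO * phi * rho_solute)
  c_num <- mass_conc * N_AVOGADRO / Mw
  f <- function(log10_dg) {
    ln_nucleation_rate(gamma = gamma, delta_g = -10^log10_dg, vm = vm,
                       c_num = c_num, D = D, theta = theta, T = T) -
      log(threshold)
  }
  lo <- -30; hi <- -15
  if (f(lo) > 0 || f(hi) < 0) {
    stop("no root in the driving-force bracket [1e-30, 1e-15] J")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  10^root * N_AVOGADRO
}

#' Expected number of nuclei forming in a cell
#'
#' \eqn{N = J(\Delta g, \gamma) \cdot V \cdot \Delta t} with cell volume
#' \eqn{V = (\pi/6) d^3} and the diffusive depletion time
#' \eqn{\Delta t = d^2/(6D)}: the window during which a driving force
#' persists before transport levels it out.
#'
#' @param delta_g driving force magnitude (J/mol)
#' @param gamma interfacial tension (J/m^2)
#' @param d_cell cell diameter (m), default 60 um
#' @param D solute diffusivity in the cell (m^2/s), default 1e-10
#' @param Mw,phi,mass_conc,T,rho_solute,theta atlas reference parameters,
#'   as in [delta_g_min()]
#' @return expected number of nuclei (dimensionless), vectorised over
#'   `delta_g`
#' @export
cell_nuclei <- function(delta_g, gamma, d_cell = 60e-6, D = 1e-10,
                        Mw = 2500, phi = 0.2, mass_conc = 1, T = 300,
                        rho_solute = 1500, theta = 1) {
  stopifnot(all(delta_g >= 0), gamma > 0, d_cell > 0)
  vm <- Mw / (N_AVOGADRO * phi * rho_solute)
  c_num <- mass_conc * N_AVOGADRO / Mw
  V <- pi / 6 * d_cell^3
  dt <- d_cell^2 / (6 * D)
  lnJ <- ln_nucleation_rate(gamma = gamma,
                            delta_g = -delta_g / N_AVOGADRO, vm = vm,
                            c_num = c_num, D = D, theta = theta, T = T)
  ifelse(lnJ < -700, 0, exp(lnJ)) * V * dt
}

#' Surface-area scaling with the number of condensates
#'
#' At fixed total condensed mass, splitting it over `n_ratio` times more
#' condensates multiplies the total surface area by \eqn{n_{ratio}^{1/3}}
#' (each diameter shrinks by \eqn{n_{ratio}^{-1/3}}).
#'
#' @param n_ratio ratio of condensate numbers (> 0)
#' @return total surface-area ratio
#' @examples
#' surface_area_factor(1000) # 10
#' @export
surface_area_factor <- function(n_ratio) {
  stopifnot(all(n_ratio > 0))
  n_ratio^(1 / 3)
}

#' Read a tension atlas from CSV
#'
#' Expected columns: `system`, `gamma_low_uJ_per_m2`, `gamma_high_uJ_per_m2`,
#' `Mw_kg_per_mol`, `class` (`"condensate"` or `"solid"`), optional `phi`.
#'
#' @param path CSV file path
#' @return data.frame with `system`, `gamma_low`/`gamma_high` (J/m^2), `Mw`
#'   (kg/mol), `klass`, `phi`
#' @export
read_tension_atlas <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("system", "gamma_low_uJ_per_m2", "gamma_high_uJ_per_m2",
            "Mw_kg_per_mol", "class")
  if (!all(need %in% names(d))) {
    stop("tension atlas CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(d$class %in% c("condensate", "solid"))) {
    stop("`class` must be 'condensate' or 'solid'")
  }
  if (any(d$gamma_low_uJ_per_m2 > d$gamma_high_uJ_per_m2)) {
    stop("gamma_low must not exceed gamma_high")
  }
  out <- data.frame(system = d$system,
                    gamma_low = d$gamma_low_uJ_per_m2 * 1e-6,
                    gamma_high = d$gamma_high_uJ_per_m2 * 1e-6,
                    Mw = d$Mw_kg_per_mol,
                    klass = d$class)
  out$phi <- if ("phi" %in% names(d)) d$phi else
    ifelse(out$klass == "solid", 0.5, 0.2)
  out
}

#' Nucleation-propensity atlas
#'
#' Evaluates [delta_g_min()] at both ends of each system's tension range
#' under the shared reference parameter set. Condensate systems (tensions of
#' order uJ/m^2) reach relevant nucleation rates at driving forces below the
#' thermal energy RT, while solids (mJ/m^2 tensions) require far larger
#' driving forces: the physical separation behind the distinct assembly
#' kinetics of condensates and solid aggregates.
#'
#' @param atlas data.frame from [read_tension_atlas()]
#' @param ... further arguments passed to [delta_g_min()]
#' @return the atlas with columns `dg_min_low`, `dg_min_high` (J/mol,
#'   evaluated at `gamma_low` and `gamma_high`) appended
#' @export
atlas_delta_g_min <- function(atlas, ...) {
  atlas$dg_min_low <- mapply(function(g, mw, ph)
    delta_g_min(g, Mw = mw, phi = ph, ...),
    atlas$gamma_low, atlas$Mw, atlas$phi)
  atlas$dg_min_high <- mapply(function(g, mw, ph)
    delta_g_min(g, Mw = mw, phi = ph, ...),
    atlas$gamma_high, atlas$Mw, atlas$phi)
  atlas
}
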