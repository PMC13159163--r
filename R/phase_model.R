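#' Binary Flory-Huggins phase model
#'
#' Describes a polymer-solvent mixture by the mean-field free energy per
#' lattice site (in units of \eqn{k_B T})
#' \deqn{f(\phi, T) = \phi \ln(\phi)/M + (1-\phi)\ln(1-\phi) +
#'   \chi(T)\,\phi(1-\phi)}
#' with an effective chain length `M` and a temperature-dependent
#' interaction parameter \eqn{\chi(T) = A + B/T}. `A` collects entropic
#' contributions, `B` (in kelvin) the effective pairwise interaction energy.
#' `rho_solute` (kg/m^3) converts between solute volume fraction and mass
#' concentration.
#'
#' @param M effective chain length (dimensionless, >= 1)
#' @param A entropic part of the interaction parameter (dimensionless)
#' @param B enthalpic part of the interaction parameter (kelvin)
#' @param rho_solute solute mass density (kg/m^3), default 1600 for RNA
#' @return an object of class `phase_model`
#' @examples
#' m <- phase_model(M = 2000, A = 0.23, B = 98.8)
#' critical_point(m)
#' @export
phase_model <- function(M, A, B, rho_solute = 1600) {
  stopifnot(is.numeric(M), length(M) == 1, M >= 1,
            is.numeric(A), length(A) == 1, is.finite(A),
            is.numeric(B), length(B) == 1, is.finite(B),
            is.numeric(rho_solute), length(rho_solute) == 1, rho_solute > 0)
  structure(list(M = M, A = A, B = B, rho_solute = rho_solute),
            class = "phase_model")
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf("Flory-Huggins phase model: M = %g, chi(T) = %g + %g K / T, rho_solute = %g kg/m^3\n",
              x$M, x$A, x$B, x$rho_solute))
  cp <- tryCatch(critical_point(x), error = function(e) NULL)
  if (!is.null(cp)) {
    cat(sprintf("  critical point: phi_c = %.4g, T_c = %.2f K (%.1f C)\n",
                cp$phi_c, cp$T_c, kelvin_to_celsius(cp$T_c)))
  }
  invisible(x)
}

#' Interaction parameter at temperature T
#'
#' @param T temperature (K)
#' @param model a [phase_model()]
#' @return \eqn{\chi(T) = A + B/T} (vectorised over `T`)
#' @export
chi_at <- function(T, model) {
  stopifnot(all(T > 0))
  model$A + model$B / T
}

#' Flory-Huggins free energy per lattice site
#'
#' Returns \eqn{f/(k_B T) = \phi\ln\phi/M + (1-\phi)\ln(1-\phi) +
#' \chi(T)\phi(1-\phi)}. The entropy terms are continuously extended with
#' \eqn{x \ln x \to 0} at \eqn{x = 0}, so `phi = 0` and `phi = 1` are valid.
#'
#' @param phi solute volume fraction, in `[0, 1]` (vectorised)
#' @param T temperature (K)
#' @param model a [phase_model()]
#' @return dimensionless free energy density (units of k_B T per site)
#' @export
free_energy_density <- function(phi, T, model) {
  if (any(phi < 0 | phi > 1)) {
    stop("`phi` must lie in [0, 1]")
  }
  chi <- chi_at(T, model)
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  xlx(phi) / model$M + xlx(1 - phi) + chi * phi * (1 - phi)
}

# First and second phi-derivatives of f, used by the binodal solver.
fh_fprime <- function(phi, chi, M) {
  (log(phi) + 1) / M - log(1 - phi) - 1 + chi * (1 - 2 * phi)
}

fh_fsecond <- function(phi, chi, M) {
  1 / (M * phi) + 1 / (1 - phi) - 2 * chi
}

#' Free energy per solute molecule
#'
#' Rescales the per-site free energy to a per-molecule basis,
#' \eqn{g = f M / \phi} (units of k_B T per solute molecule).
#'
#' @inheritParams free_energy_density
#' @return dimensionless free energy per solute molecule (k_B T units)
#' @export
per_molecule_free_energy <- function(phi, T, model) {
  if (any(phi <= 0)) stop("`phi` must be positive for a per-molecule energy")
  free_energy_density(phi, T, model) * model$M / phi
}

#' Critical point of the Flory-Huggins model
#'
#' Closed form for the binary model: \eqn{\phi_c = 1/(1+\sqrt{M})},
#' \eqn{\chi_c = (1 + 1/\sqrt{M})^2 / 2}; the critical temperature solves
#' \eqn{A + B/T_c = \chi_c}.
#'
#' @param model a [phase_model()]
#' @return list with `phi_c`, `chi_c`, `T_c` (K)
#' @export
critical_point <- function(model) {
  if (model$B == 0) stop("B = 0: chi does not depend on temperature")
  phi_c <- 1 / (1 + sqrt(model$M))
  chi_c <- (1 + 1 / sqrt(model$M))^2 / 2
  T_c <- model$B / (chi_c - model$A)
  if (T_c <= 0) {
    stop("no finite positive critical temperature for this parameterisation")
  }
  list(phi_c = phi_c, chi_c = chi_c, T_c = T_c)
}

#' Convert mass concentration to volume fraction (and back)
#'
#' \eqn{\phi = c / \rho_{solute}}; the inverse is an exact round trip.
#'
#' @param conc mass concentration (kg/m^3)
#' @param phi volume fraction in `[0, 1]`
#' @param model a [phase_model()] carrying `rho_solute`
#' @return volume fraction, or mass concentration (kg/m^3)
#' @export
phi_from_conc <- function(conc, model) {
  if (any(conc < 0)) stop("`conc` must be non-negative")
  if (any(conc > model$rho_solute)) {
    stop("`conc` exceeds the solute density; volume fraction would exceed 1")
  }
  conc / model$rho_solute
}

#' @rdname phi_from_conc
#' @export
conc_from_phi <- function(phi, model) {
  if (any(phi < 0 | phi > 1)) stop("`phi` must lie in [0, 1]")
  phi * model$rho_solute
}

#' Published Flory-Huggins parameterisations for poly-rA RNA in 1 M KCl
#'
#' Three chain-length parameterisations fitted to the same binodal data;
#' `m2000` is the reference set, `m1000` and `m4000` bracket the uncertainty
#' associated with the choice of effective chain length.
#'
#' @param name one of `"m1000"`, `"m2000"`, `"m4000"`
#' @return a [phase_model()]
#' @examples
#' fh_preset("m2000")
#' @export
fh_preset <- function(name = c("m2000", "m1000", "m4000")) {
  name <- match.arg(name)
  p <- fh_preset_table()[[name]]
  phase_model(M = p$M, A = p$A, B = p$B, rho_solute = p$rho_solute)
}

fh_preset_table <- function() {
  path <- system.file("extdata", "presets.json", package = "condnuc")
  jsonlite::fromJSON(path, simplifyVector = FALSE)$phase_models
}
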