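# Classical nucleation theory machinery.
#
# The rate is assembled as the product J = theta * z * f_c * rho_m *
# exp(-W_c / kB T) (stationary CNT): the product form is authoritative and
# the collapsed closed form
#   J = theta * D * c * |dg| / (vm * sqrt(gamma kB T)) * exp(-W_c / kB T)
# is a verified identity, not an independent input. Driving forces are
# stored signed (favourable = negative); J is defined as 0 for dg >= 0.

#' Kinetic parameters for nucleation rates
#'
#' @param theta dimensionless kinetic prefactor (correction factor); of order
#'   one for homogeneous, volume-diffusion-limited nucleation
#' @param D_plus dense-phase solute diffusivity (m^2/s)
#' @param D_minus dilute-phase solute diffusivity (m^2/s); typically
#'   about 1000 x `D_plus` for condensates
#' @param Mw solute molecular weight (kg/mol)
#' @return an object of class `kinetic_params`
#' @examples
#' kinetic_params(theta = 1.5e-10, D_plus = 1.3e-13, D_minus = 1.3e-10,
#'                Mw = 2500)
#' @export
kinetic_params <- function(theta, D_plus, D_minus = 1000 * D_plus, Mw) {
  stopifnot(theta >= 0, D_plus > 0, D_minus > 0, Mw > 0)
  structure(list(theta = theta, D_plus = D_plus, D_minus = D_minus, Mw = Mw),
            class = "kinetic_params")
}

#' Volume per solute molecule from a mass concentration
#'
#' \eqn{v_m = M_w / (N_A \hat c)}: the average volume of phase in which one
#' solute molecule resides, given the phase's solute mass concentration.
#'
#' @param mass_conc solute mass concentration of the phase (kg/m^3), > 0
#' @param Mw molecular weight (kg/mol)
#' @return molecular volume (m^3), vectorised
#' @export
molecular_volume <- function(mass_conc, Mw) {
  if (any(mass_conc <= 0)) stop("`mass_conc` must be positive")
  Mw / (N_AVOGADRO * mass_conc)
}

#' Nucleation context: the local quantities a CNT rate depends on
#'
#' @param gamma interfacial tension (J/m^2), > 0
#' @param delta_g driving force per molecule (J), signed
#'   (favourable = negative)
#' @param vm volume per solute molecule in the *nucleating* phase (m^3)
#' @param c_num number concentration of solute in the *parent* phase (m^-3)
#' @param T temperature (K)
#' @return an object of class `nucleation_context`
#' @export
nucleation_context <- function(gamma, delta_g, vm, c_num, T) {
  stopifnot(gamma > 0, vm > 0, c_num >= 0, T > 0)
  structure(list(gamma = gamma, delta_g = delta_g, vm = vm,
                 c_num = c_num, T = T),
            class = "nucleation_context")
}

# geometric constant for the area of a sphere of volume n*vm:
# A(n) = (36 pi)^(1/3) vm^(2/3) n^(2/3)
AREA_CONST <- (36 * pi)^(1 / 3)

#' Work of forming a cluster of n molecules
#'
#' \eqn{W(n) = \gamma (36\pi)^{1/3} v_m^{2/3} n^{2/3} + n \Delta g} for a
#' spherical cluster; positive at small n, a single maximum at the critical
#' size, negative beyond.
#'
#' @param n cluster size (molecules, >= 0, need not be integer); vectorised
#' @param ctx a [nucleation_context()] with `delta_g < 0`
#' @return cluster work (J)
#' @export
cluster_work <- function(n, ctx) {
  if (any(n < 0)) stop("`n` must be non-negative")
  if (ctx$delta_g >= 0) {
    stop("no nucleation barrier: `delta_g` must be negative")
  }
  ctx$gamma * AREA_CONST * ctx$vm^(2 / 3) * n^(2 / 3) + n * ctx$delta_g
}

#' Critical cluster size (molecules)
#'
#' Size at the maximum of [cluster_work()]:
#' \eqn{n_c = (32\pi/3)\gamma^3 v_m^2 / |\Delta g|^3}.
#'
#' @inheritParams cluster_work
#' @return critical size (molecules)
#' @export
critical_size_molecules <- function(ctx) {
  if (ctx$delta_g == 0) stop("delta_g = 0: infinite critical size")
  (32 * pi / 3) * ctx$gamma^3 * ctx$vm^2 / abs(ctx$delta_g)^3
}

#' Work of forming the critical cluster
#'
#' \eqn{W_c = (16\pi/3)\, \gamma^3 v_m^2 / \Delta g^2}: the nucleation
#' barrier, cubic in the tension and inverse-square in the driving force.
#'
#' @inheritParams cluster_work
#' @return barrier height (J)
#' @export
critical_work <- function(ctx) {
  if (ctx$delta_g == 0) stop("delta_g = 0: the nucleation barrier is infinite")
  (16 * pi / 3) * ctx$gamma^3 * ctx$vm^2 / ctx$delta_g^2
}

#' Critical cluster radius
#'
#' \eqn{r_c = 2 \gamma v_m / |\Delta g|} (Gibbs-Thomson radius); of order
#' 10-100 nm for condensates under experimentally relevant conditions.
#'
#' @inheritParams cluster_work
#' @return radius (m)
#' @export
critical_radius <- function(ctx) {
  if (ctx$delta_g == 0) stop("delta_g = 0: infinite critical radius")
  2 * ctx$gamma * ctx$vm / abs(ctx$delta_g)
}

#' Zeldovich factor
#'
#' \eqn{z = \sqrt{-W''(n_c) / (2\pi k_B T)}}, the correction for the
#' non-equilibrium cluster-size distribution near the critical size.
#' Evaluated from the curvature of [cluster_work()]; equal to the closed
#' form \eqn{z = \Delta g^2 / (8\pi v_m \sqrt{\gamma^3 k_B T})} for the
#' spherical-cluster area law.
#'
#' @inheritParams cluster_work
#' @return dimensionless Zeldovich factor
#' @export
zeldovich <- function(ctx) {
  nc <- critical_size_molecules(ctx)
  # W''(n) = -(2/9) gamma (36 pi)^(1/3) vm^(2/3) n^(-4/3)
  wpp <- -(2 / 9) * ctx$gamma * AREA_CONST * ctx$vm^(2 / 3) * nc^(-4 / 3)
  sqrt(-wpp / (2 * pi * KB * ctx$T))
}

#' Monomer attachment frequency at the critical size
#'
#' Volume-diffusion-limited attachment:
#' \eqn{f_c = (48\pi^2 v_m)^{1/3} c D n_c^{1/3}}, algebraically equal to
#' \eqn{8\pi c D \gamma v_m / |\Delta g|}.
#'
#' @inheritParams cluster_work
#' @param D diffusivity of the solute in the parent phase (m^2/s)
#' @return attachment frequency (1/s)
#' @export
attachment_frequency <- function(ctx, D) {
  nc <- critical_size_molecules(ctx)
  (48 * pi^2 * ctx$vm)^(1 / 3) * ctx$c_num * D * nc^(1 / 3)
}

# log nucleation rate, vectorised core used by sweeps and field evaluation.
# Arguments are plain vectors (recycled to the longest); returns ln J with
# -Inf where the driving force is non-negative. theta multiplies the
# prefactor.
ln_nucleation_rate <- function(gamma, delta_g, vm, c_num, D, theta, T) {
  n <- max(length(gamma), length(delta_g), length(vm), length(c_num),
           length(D), length(T))
  gamma <- rep_len(gamma, n); delta_g <- rep_len(delta_g, n)
  vm <- rep_len(vm, n); c_num <- rep_len(c_num, n)
  D <- rep_len(D, n); T <- rep_len(T, n)
  ln_j <- rep(-Inf, n)
  ok <- delta_g < 0 & gamma > 0 & c_num > 0
  if (!any(ok)) return(ln_j)
  g <- gamma[ok]
  dg <- abs(delta_g[ok])
  v <- vm[ok]
  TT <- T[ok]
  wc <- (16 * pi / 3) * g^3 * v^2 / dg^2
  # collapsed z * f_c * rho_m = c D |dg| / (vm sqrt(gamma kB T))
  ln_j[ok] <- log(theta * D[ok] * c_num[ok] * dg) -
    log(v) - 0.5 * log(g * KB * TT) - wc / (KB * TT)
  ln_j
}

#' Stationary nucleation rate
#'
#' Assembles \eqn{J = \vartheta\, z f_c \rho_m \exp(-W_c / k_B T)} with
#' \eqn{\rho_m = 1/v_m}, from [zeldovich()], [attachment_frequency()] and
#' [critical_work()]. Returns 0 when the driving force is non-negative
#' (no supersaturation, no nucleation) or on underflow of the Boltzmann
#' factor (the log-rate is computed first and exponentiated last).
#'
#' For `which = "void"` the context must hold the dense-phase parent
#' concentration, the dilute-phase molecular volume and \eqn{\Delta g_-}
#' (dense-phase diffusivity is used); for `which = "condensate"` the
#' dilute-phase concentration, dense-phase molecular volume and
#' \eqn{\Delta g_+} (dilute-phase diffusivity).
#'
#' @inheritParams cluster_work
#' @param kin a [kinetic_params()]
#' @param which `"void"` or `"condensate"`; selects the diffusivity
#' @return nucleation rate (m^-3 s^-1)
#' @export
nucleation_rate <- function(ctx, kin, which = c("void", "condensate")) {
  which <- match.arg(which)
  if (ctx$gamma <= 0) stop("`gamma` must be positive")
  if (ctx$delta_g >= 0) return(0)
  D <- if (which == "void") kin$D_plus else kin$D_minus
  z <- zeldovich(ctx)
  fc <- attachment_frequency(ctx, D)
  rho_m <- 1 / ctx$vm
  ln_j <- log(kin$theta) + log(z) + log(fc) + log(rho_m) -
    critical_work(ctx) / (KB * ctx$T)
  if (ln_j < -700) return(0)
  exp(ln_j)
}
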