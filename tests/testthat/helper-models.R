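# Shared fixtures: the reference poly-rA parameterisation, kinetic
# parameters, and a coarsened transport configuration that keeps the
# diffusion simulations fast in tests (convergence towards the default
# resolution is itself tested in test-transport.R).

m2000 <- phase_model(M = 2000, A = 0.23, B = 98.8, rho_solute = 1600)

kin_ref <- kinetic_params(theta = 1.5e-10, D_plus = 1.3e-13,
                          D_minus = 1.3e-10, Mw = 2500)

T0_REF <- celsius_to_kelvin(55)
TEND_REF <- celsius_to_kelvin(36)

# coarse-but-converged transport settings for test-speed simulations
tp_fast <- list(n_grid = 150, dT_step = 0.1, save_every = 4)

# chi fixed at `chi` for any temperature near T = 300 K
model_with_chi <- function(chi, M = 1, rho = 1000) {
  phase_model(M = M, A = 0, B = chi * 300, rho_solute = rho)
}

kbt <- function(T) 1.380649e-23 * T
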