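# Flory-Huggins free energies, binodal construction, critical point,
# concentration conversions, driving forces and tension models.

test_that("free energy density matches hand-evaluated values and limits", {
  m1 <- model_with_chi(2)
  # phi ln phi and (1-phi) ln(1-phi) extended by 0 at the endpoints
  expect_identical(free_energy_density(0, 300, m1), 0)
  expect_equal(free_energy_density(1, 300, m1), 0)
  # M=1, chi=2, phi=0.5: ln(0.5) + 0.5
  expect_equal(free_energy_density(0.5, 300, m1), -0.19314718056, tolerance = 1e-10)
  # M=1 free energy is symmetric about phi = 1/2 for any chi
  phis <- seq(0.05, 0.95, by = 0.05)
  m_asym <- model_with_chi(1.3)
  expect_equal(free_energy_density(phis, 300, m_asym),
               free_energy_density(1 - phis, 300, m_asym), tolerance = 1e-12)
  expect_error(free_energy_density(-0.1, 300, m1), "phi")
  expect_error(free_energy_density(1.1, 300, m1), "phi")
})

test_that("per-molecule free energy is f*M/phi with the right limits", {
  m1 <- model_with_chi(2)
  expect_equal(per_molecule_free_energy(0.5, 300, m1), 2 * (-0.19314718056),
               tolerance = 1e-10)
  # algebraic identity g * phi / M = f at a long chain length
  m <- m2000
  phis <- c(1e-4, 0.01, 0.1, 0.5)
  expect_equal(per_molecule_free_energy(phis, 310, m) * phis / m$M,
               free_energy_density(phis, 310, m), tolerance = 1e-12)
  # pure-solute limit: entropy terms vanish as phi -> 1
  expect_lt(abs(per_molecule_free_energy(1 - 1e-12, 300, m1)), 1e-9)
  expect_error(per_molecule_free_energy(0, 300, m1), "positive")
})

test_that("critical point closed forms are exact", {
  expect_equal(critical_point(model_with_chi(1, M = 1))$phi_c, 0.5)
  expect_equal(critical_point(model_with_chi(1, M = 1))$chi_c, 2)
  cp100 <- critical_point(phase_model(M = 100, A = 0.1, B = 200))
  expect_equal(cp100$phi_c, 1 / 11, tolerance = 1e-12)
  expect_equal(cp100$chi_c, 0.605, tolerance = 1e-12)
  # the poly-rA parameterisation: T_c = 64.5 C
  cp <- critical_point(m2000)
  expect_equal(kelvin_to_celsius(cp$T_c), 64.5, tolerance = 1e-4)
  expect_error(critical_point(phase_model(M = 1, A = 3, B = 10)), "critical")
})

test_that("binodal agrees with the symmetric-blend bisection oracle", {
  # for M = 1, the coexistence condition reduces to
  # ln(phi/(1-phi)) = chi (2 phi - 1); solve by bisection, independently
  chi <- 2.5
  m1 <- model_with_chi(chi)
  oracle <- uniroot(function(p) log(p / (1 - p)) - chi * (2 * p - 1),
                    c(1e-8, 0.499999), tol = 1e-14)$root
  b <- compute_binodal(300, m1)
  expect_equal(b$phi_minus, oracle, tolerance = 1e-8)
  expect_equal(b$phi_plus, 1 - oracle, tolerance = 1e-8)
})

test_that("binodal satisfies the common-tangent conditions to 1e-8", {
  cases <- list(list(m = m2000, T = 309.15), list(m = m2000, T = 328.15),
                list(m = model_with_chi(2.2), T = 300),
                list(m = phase_model(M = 50, A = 0.1, B = 250), T = 300))
  for (cs in cases) {
    b <- compute_binodal(cs$T, cs$m)
    chi <- chi_at(cs$T, cs$m)
    fp <- function(p) (log(p) + 1) / cs$m$M - log(1 - p) - 1 + chi * (1 - 2 * p)
    f <- function(p) free_energy_density(p, cs$T, cs$m)
    expect_lt(abs(fp(b$phi_minus) - fp(b$phi_plus)), 1e-8)
    expect_lt(abs(f(b$phi_plus) - f(b$phi_minus) -
                    fp(b$phi_minus) * (b$phi_plus - b$phi_minus)), 1e-8)
  }
})

test_that("M=1 binodal is symmetric and the gap shrinks towards T_c", {
  m1 <- model_with_chi(2.4)
  b <- compute_binodal(300, m1)
  expect_lt(abs(b$phi_minus + b$phi_plus - 1), 1e-9)

  # binodal gap is monotonically non-increasing in T up to T_c
  cp <- critical_point(m2000)
  Ts <- seq(283.15, cp$T_c + 2, length.out = 60)
  bc <- binodal_curve(Ts, m2000)
  gap <- bc$phi_plus - bc$phi_minus
  expect_true(all(diff(gap) <= 1e-12))
  # dense binodal widens upon cooling: phi+ at 36 C > phi+ at 55 C
  expect_gt(bc$phi_plus[1], bc$phi_plus[30])

  # at and above T_c the binodal degenerates to the critical composition
  b_hot <- compute_binodal(cp$T_c + 5, m2000)
  expect_equal(b_hot$phi_minus, cp$phi_c)
  expect_equal(b_hot$phi_plus, cp$phi_c)
  b_at <- compute_binodal(cp$T_c, m2000)
  expect_equal(b_at$phi_minus, b_at$phi_plus)
})

test_that("binodal degeneracy temperature matches the closed-form T_c", {
  cp <- critical_point(m2000)
  dT <- 0.05
  Ts <- seq(cp$T_c - 20 * dT, cp$T_c + 5 * dT, by = dT)
  bc <- binodal_curve(Ts, m2000)
  gap <- bc$phi_plus - bc$phi_minus
  # the hull/Newton construction closes within a few grid steps of T_c
  T_degen <- min(Ts[gap < 1e-6])
  expect_lt(abs(T_degen - cp$T_c), 5 * dT)
})

test_that("concentration conversions are exact round trips", {
  expect_equal(phi_from_conc(0, m2000), 0)
  expect_equal(phi_from_conc(1600, m2000), 1)
  expect_equal(phi_from_conc(0.82, m2000), 5.125e-4)
  phis <- c(0, 1e-6, 0.2, 1)
  expect_equal(phi_from_conc(conc_from_phi(phis, m2000), m2000), phis)
  expect_error(phi_from_conc(1700, m2000), "density")
  expect_error(conc_from_phi(1.2, m2000), "phi")
})

test_that("condensate driving force delta_g_plus follows -kBT ln S", {
  T <- 313.15
  pm <- compute_binodal(T, m2000)$phi_minus
  expect_equal(delta_g_plus(pm, T, m2000), 0, tolerance = 1e-25)
  expect_equal(delta_g_plus(exp(1) * pm, T, m2000), -kbt(T), tolerance = 1e-12)
  # undersaturated solutions have a positive (unfavourable) driving force
  expect_equal(delta_g_plus(pm / 2, T, m2000), kbt(T) * log(2),
               tolerance = 1e-12)
  expect_error(delta_g_plus(0, T, m2000), "positive")
})

test_that("partition factor matches hand arithmetic and limit behaviour", {
  expect_equal(partition_factor(0.2, 0.1, 0.5), 5 / 3, tolerance = 1e-12)
  expect_lt(partition_factor(0.1 + 1e-9, 0.1, 0.5), 1e-6)
  expect_gt(partition_factor(0.5 - 1e-9, 0.1, 0.5), 1e6)
  expect_error(partition_factor(0.05, 0.1, 0.5), "between")
  expect_error(partition_factor(0.6, 0.1, 0.5), "between")
})

test_that("void driving force vanishes at both binodals, negative between", {
  T <- 313.15
  b <- compute_binodal(T, m2000)
  expect_identical(delta_g_minus(b$phi_minus, T, m2000, b), 0)
  expect_identical(delta_g_minus(b$phi_plus, T, m2000, b), 0)
  phis <- seq(b$phi_minus * 1.001, b$phi_plus * 0.999, length.out = 400)
  dg <- delta_g_minus(phis, T, m2000, b)
  expect_true(all(dg < 0))
  # approaches zero towards both ends (the dense-side approach is linear
  # with a steep slope, so probe very close to the binodal there)
  expect_gt(dg[1], min(dg) * 1e-3)
  expect_gt(delta_g_minus(b$phi_plus * 0.99999, T, m2000, b), min(dg) * 1e-3)
  expect_error(delta_g_minus(b$phi_plus * 1.05, T, m2000, b), "binodal")
})

test_that("void driving force has exactly one interior minimum", {
  for (T in c(303.15, 313.15, 323.15)) {
    b <- compute_binodal(T, m2000)
    phis <- seq(b$phi_minus * 1.01, b$phi_plus * 0.9999, length.out = 800)
    dg <- delta_g_minus(phis, T, m2000, b)
    sign_changes <- sum(abs(diff(sign(diff(dg)))) > 0)
    expect_equal(sign_changes, 1)
  }
})

test_that("tangent-excess form agrees with the naive two-term formula", {
  # mid-interval, where the naive evaluation is well conditioned
  T <- 313.15
  b <- compute_binodal(T, m2000)
  phis <- seq(b$phi_minus * 2, b$phi_plus * 0.95, length.out = 20)
  g <- function(x) per_molecule_free_energy(x, T, m2000)
  K <- partition_factor(phis, b$phi_minus, b$phi_plus)
  naive <- ((g(b$phi_minus) - g(phis)) + K * (g(b$phi_plus) - g(phis))) * kbt(T)
  expect_equal(delta_g_minus(phis, T, m2000, b), naive, tolerance = 1e-6)
})

test_that("tension models evaluate their scaling forms", {
  tc <- tension_model("constant", gamma0 = 2e-6)
  expect_equal(gamma_at(c(280, 310, 340), tc), rep(2e-6, 3))

  ti <- tension_model("ising_T", gamma0 = 1, Tc = 337.65)
  expect_equal(gamma_at(312.15, ti), 0.0385809144589, tolerance = 1e-9)
  expect_equal(gamma_at(337.65, ti), 0)
  expect_error(gamma_at(350, ti), "critical")

  tg <- tension_model("binodal_gap", gamma0 = 1e-4)
  T <- c(303.15, 323.15)
  bc <- binodal_curve(T, m2000)
  expect_equal(gamma_at(T, tg, m2000),
               1e-4 * (bc$phi_plus - bc$phi_minus)^3.9, tolerance = 1e-10)
  # gap form vanishes at the critical temperature too
  expect_equal(gamma_at(critical_point(m2000)$T_c, tg, m2000), 0)
})

test_that("binodal fit recovers the generating (A, B) from clean data", {
  pts <- gen_binodal_points(m2000, temps_C = seq(20, 60, 5), rel_noise = 0,
                            seed = 1)
  fit <- fit_phase_model(pts, M = 2000, rho_solute = 1600)
  expect_equal(fit$A, 0.23, tolerance = 1e-5)
  expect_equal(fit$B, 98.8, tolerance = 1e-4)
  expect_equal(kelvin_to_celsius(fit$T_c), 64.5, tolerance = 0.01)
  # dense-only weighting also identifies the parameters on clean data
  fitd <- fit_phase_model(pts, M = 2000, weighting = "dense")
  expect_equal(fitd$A, 0.23, tolerance = 1e-4)
})
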