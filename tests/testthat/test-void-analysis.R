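# Expected void counts, nucleation frequency, Poisson statistics, critical
# sizes and the (gamma0, theta) fit.

tension_ref <- tension_model("constant", gamma0 = 1.8e-6)

test_that("Poisson void probabilities", {
  expect_equal(poisson_void_probability(1, 1), exp(-1), tolerance = 1e-12)
  expect_equal(poisson_void_probability(0, 0), 1)
  expect_equal(sum(poisson_void_probability(2.7, 0:60)), 1, tolerance = 1e-12)
  expect_error(poisson_void_probability(-1, 0), "N")
})

test_that("rate-field quadrature reproduces the closed-form constant case", {
  # constant J over a non-shrinking sphere: N = J * (4/3) pi R^3 * t
  iso <- cooling_protocol(T0_REF, T0_REF, rate = 5 / 60)
  tr <- simulate_condensate(20e-6, iso, m2000, D = 1.3e-13, n_grid = 100,
                            max_steps = 120, dt_hold = 1)
  tr$times <- tr$times * (100 / max(tr$times)) # rescale to a 100 s window
  out <- integrate_rate_field(tr, function(conc, T, pm, pp) {
    rep(1e12, length(conc))
  })
  expect_equal(out$N, 3.35103216383, tolerance = 0.005)
  # and an equilibrium trajectory yields exactly zero physical voids
  expect_equal(expected_voids(tr, tension_ref, kin_ref), 0)
  nf <- nucleation_frequency(tr, tension_ref, kin_ref)
  expect_true(all(nf$K == 0))
})

test_that("nucleation frequency peaks at ramp end; integral matches N", {
  tr <- simulate_condensate(15e-6, cooling_protocol(T0_REF, TEND_REF, 5 / 60),
                            m2000, D = 1.3e-13, n_grid = 150, dT_step = 0.1)
  nf <- nucleation_frequency(tr, tension_ref, kin_ref)
  expect_true(all(nf$K >= 0))
  t_ramp <- (T0_REF - TEND_REF) / (5 / 60)
  expect_equal(nf$time[which.max(nf$K)], t_ramp, tolerance = 0.05)
  # trapezoid integral of K(t) equals expected_voids by construction of the
  # shared quadrature
  N_from_K <- sum((nf$K[-1] + nf$K[-nrow(nf)]) / 2 * diff(nf$time))
  expect_equal(N_from_K, expected_voids(tr, tension_ref, kin_ref),
               tolerance = 1e-6)
})

test_that("expected voids increase with size and with cooling rate", {
  N_at <- function(d, rate) {
    condnuc:::expected_voids_at_diameter(d, rate, m2000, tension_ref,
                                         kin_ref, T0_REF, TEND_REF, tp_fast)
  }
  Ns <- sapply(c(12e-6, 20e-6, 35e-6, 60e-6), N_at, rate = 2 / 60)
  expect_true(all(diff(Ns) > 0))
  # faster cooling gives more voids at fixed size
  expect_gt(N_at(20e-6, 5 / 60), N_at(20e-6, 1 / 60))
})

test_that("expected voids converge under combined resolution refinement", {
  # the scheme is first order in the combined grid/time step; at the
  # default-scale resolution a further doubling moves N by less than 2%
  N_at <- function(n_grid, dT_step) {
    condnuc:::expected_voids_at_diameter(
      25e-6, 2 / 60, m2000, tension_ref, kin_ref, T0_REF, TEND_REF,
      list(n_grid = n_grid, dT_step = dT_step))
  }
  expect_equal(N_at(300, 0.05), N_at(600, 0.025), tolerance = 0.02)
})

test_that("critical size brackets to its target and decreases with rate", {
  cs_fast <- critical_size(5 / 60, m2000, tension_ref, kin_ref, T0_REF,
                           TEND_REF, transport = tp_fast)
  expect_equal(cs_fast$N_at_crit, 1, tolerance = 0.05)
  N_check <- condnuc:::expected_voids_at_diameter(
    cs_fast$d_crit, 5 / 60, m2000, tension_ref, kin_ref, T0_REF, TEND_REF,
    tp_fast)
  expect_equal(N_check, 1, tolerance = 0.05)
  cs_slow <- critical_size(1 / 60, m2000, tension_ref, kin_ref, T0_REF,
                           TEND_REF, transport = tp_fast)
  expect_gt(cs_slow$d_crit, cs_fast$d_crit)
  # both inside the experimental observation window
  expect_gt(cs_fast$d_crit, 10e-6)
  expect_lt(cs_slow$d_crit, 100e-6)
})

test_that("the Poisson band brackets the critical size", {
  cs <- critical_size(5 / 60, m2000, tension_ref, kin_ref, T0_REF, TEND_REF,
                      band = TRUE, transport = tp_fast)
  expect_lt(cs$band_low, cs$d_crit)
  expect_gt(cs$band_high, cs$d_crit)
})

test_that("fit objective is near zero at the generating parameters and is
           invariant to record order", {
  sizes <- data.frame(cooling_rate = c(1, 5) / 60,
                      diameter = c(29.0e-6, 15.8e-6))
  fit <- fit_void_parameters(sizes, m2000, "constant", kin_ref, T0_REF,
                             TEND_REF, n_starts = 3, transport = tp_fast)
  expect_lt(fit$objective, 0.05)
  expect_equal(fit$gamma0, 1.8e-6, tolerance = 0.05)
  fit_rev <- fit_void_parameters(sizes[2:1, ], m2000, "constant", kin_ref,
                                 T0_REF, TEND_REF, n_starts = 3,
                                 transport = tp_fast)
  expect_equal(fit_rev$objective, fit$objective, tolerance = 1e-3)
  expect_equal(fit_rev$gamma0, fit$gamma0, tolerance = 1e-3)
})

test_that("critical-size estimators recover the generating size", {
  # records drawn around a known critical size with steep Poisson counts
  set.seed(11)
  d_true <- 25e-6
  d <- exp(runif(400, log(10e-6), log(100e-6)))
  N <- exp(12 * (log(d) - log(d_true)))
  rec <- data.frame(cooling_rate = 1 / 60, diameter = d,
                    n_voids = rpois(400, N))
  cs_single <- estimate_critical_sizes(rec, method = "single_void")
  cs_pois <- estimate_critical_sizes(rec, method = "poisson")
  expect_equal(cs_single$diameter, d_true, tolerance = 0.15)
  expect_equal(cs_pois$diameter, d_true, tolerance = 0.05)
  expect_error(estimate_critical_sizes(
    data.frame(cooling_rate = 1, diameter = 1e-5, n_voids = 0),
    method = "single_void"), "single-void")
})

test_that("void CSV round-trips through the documented schema", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(cooling_rate_K_per_min = c(0.5, 5),
                       condensate_diameter_um = c(30, 18),
                       n_voids = c(1, 2)), path, row.names = FALSE)
  rec <- read_void_csv(path)
  expect_equal(rec$cooling_rate, c(0.5, 5) / 60)
  expect_equal(rec$diameter, c(30e-6, 18e-6))
  unlink(path)
})
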